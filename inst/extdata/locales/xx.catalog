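added_modification=[Àddéd môdïfïcàtïôn {0}]
added_peptide=[Àddéd péptïdé {0}]
added_precursor=[Àddéd précürsôr {0}]
added_protein=[Àddéd prôtéïn {0}]
added_transition=[Àddéd trànsïtïôn {0}]
audit_log_disabled=[Àüdït lôggïng dïsàbléd]
audit_log_enabled=[Àüdït lôggïng énàbléd]
changed_digestion=[Chàngéd dïgéstïôn {0}]
changed_digestion_enzyme=[Chàngéd {0} frôm {1} tô {2}]
changed_digestion_max_missed_cleavages=[Chàngéd {0} frôm {1} tô {2}]
changed_document=[Chàngéd dôcümént {0}]
changed_document_settings=[Chàngéd séttïngs ({0})]
changed_document_targets=[Chàngéd tàrgéts ({0})]
changed_filter=[Chàngéd fïltér {0}]
changed_filter_ion_types=[Chàngéd {0} frôm {1} tô {2}]
changed_filter_max_mz=[Chàngéd {0} frôm {1} tô {2}]
changed_filter_min_mz=[Chàngéd {0} frôm {1} tô {2}]
changed_filter_precursor_charges=[Chàngéd {0} frôm {1} tô {2}]
changed_full_scan=[Chàngéd füll scàn {0}]
changed_full_scan_acquisition_method=[Chàngéd {0} frôm {1} tô {2}]
changed_full_scan_resolving_power=[Chàngéd {0} frôm {1} tô {2}]
changed_instrument=[Chàngéd ïnstrümént {0}]
changed_instrument_dynamic_min=[Chàngéd {0} frôm {1} tô {2}]
changed_instrument_max_mz=[Chàngéd {0} frôm {1} tô {2}]
changed_instrument_min_mz=[Chàngéd {0} frôm {1} tô {2}]
changed_modification=[Chàngéd môdïfïcàtïôn {0}]
changed_modification_mass_delta=[Chàngéd {0} frôm {1} tô {2}]
changed_modification_name=[Chàngéd {0} frôm {1} tô {2}]
changed_modifications=[Chàngéd môdïfïcàtïôns {0}]
changed_modifications_static_mods=[Chàngéd stàtïc môds ({0})]
changed_modifications_variable_mods=[Chàngéd vàrïàblé môds ({0})]
changed_peptide=[Chàngéd péptïdé {0}]
changed_peptide_precursors=[Chàngéd précürsôrs ({0})]
changed_peptide_sequence=[Chàngéd {0} frôm {1} tô {2}]
changed_peptide_settings=[Chàngéd péptïdé séttïngs {0}]
changed_peptide_settings_digestion=[Chàngéd dïgéstïôn ({0})]
changed_peptide_settings_modifications=[Chàngéd môdïfïcàtïôns ({0})]
changed_precursor=[Chàngéd précürsôr {0}]
changed_precursor_charge=[Chàngéd {0} frôm {1} tô {2}]
changed_precursor_transitions=[Chàngéd trànsïtïôns ({0})]
changed_protein=[Chàngéd prôtéïn {0}]
changed_protein_name=[Chàngéd {0} frôm {1} tô {2}]
changed_protein_peptides=[Chàngéd péptïdés ({0})]
changed_settings=[Chàngéd séttïngs {0}]
changed_settings_peptide_settings=[Chàngéd péptïdé séttïngs ({0})]
changed_settings_transition_settings=[Chàngéd trànsïtïôn séttïngs ({0})]
changed_transition=[Chàngéd trànsïtïôn {0}]
changed_transition_fragment_ion=[Chàngéd {0} frôm {1} tô {2}]
changed_transition_product_charge=[Chàngéd {0} frôm {1} tô {2}]
changed_transition_settings=[Chàngéd trànsïtïôn séttïngs {0}]
changed_transition_settings_filter=[Chàngéd fïltér ({0})]
changed_transition_settings_full_scan=[Chàngéd füll scàn ({0})]
changed_transition_settings_instrument=[Chàngéd ïnstrümént ({0})]
document_created=[Dôcümént créàtéd]
removed_modification=[Rémôvéd môdïfïcàtïôn {0}]
removed_peptide=[Rémôvéd péptïdé {0}]
removed_precursor=[Rémôvéd précürsôr {0}]
removed_protein=[Rémôvéd prôtéïn {0}]
removed_transition=[Rémôvéd trànsïtïôn {0}]
undo_added_modification=[Ündô: Àddéd môdïfïcàtïôn {0}]
undo_added_peptide=[Ündô: Àddéd péptïdé {0}]
undo_added_precursor=[Ündô: Àddéd précürsôr {0}]
undo_added_protein=[Ündô: Àddéd prôtéïn {0}]
undo_added_transition=[Ündô: Àddéd trànsïtïôn {0}]
undo_audit_log_disabled=[Ündô: Àüdït lôggïng dïsàbléd]
undo_audit_log_enabled=[Ündô: Àüdït lôggïng énàbléd]
undo_changed_digestion=[Ündô: Chàngéd dïgéstïôn {0}]
undo_changed_digestion_enzyme=[Ündô: Chàngéd {0} frôm {1} tô {2}]
undo_changed_digestion_max_missed_cleavages=[Ündô: Chàngéd {0} frôm {1} tô {2}]
undo_changed_document=[Ündô: Chàngéd dôcümént {0}]
undo_changed_document_settings=[Ündô: Chàngéd séttïngs ({0})]
undo_changed_document_targets=[Ündô: Chàngéd tàrgéts ({0})]
undo_changed_filter=[Ündô: Chàngéd fïltér {0}]
undo_changed_filter_ion_types=[Ündô: Chàngéd {0} frôm {1} tô {2}]
undo_changed_filter_max_mz=[Ündô: Chàngéd {0} frôm {1} tô {2}]
undo_changed_filter_min_mz=[Ündô: Chàngéd {0} frôm {1} tô {2}]
undo_changed_filter_precursor_charges=[Ündô: Chàngéd {0} frôm {1} tô {2}]
undo_changed_full_scan=[Ündô: Chàngéd füll scàn {0}]
undo_changed_full_scan_acquisition_method=[Ündô: Chàngéd {0} frôm {1} tô {2}]
undo_changed_full_scan_resolving_power=[Ündô: Chàngéd {0} frôm {1} tô {2}]
undo_changed_instrument=[Ündô: Chàngéd ïnstrümént {0}]
undo_changed_instrument_dynamic_min=[Ündô: Chàngéd {0} frôm {1} tô {2}]
undo_changed_instrument_max_mz=[Ündô: Chàngéd {0} frôm {1} tô {2}]
undo_changed_instrument_min_mz=[Ündô: Chàngéd {0} frôm {1} tô {2}]
undo_changed_modification=[Ündô: Chàngéd môdïfïcàtïôn {0}]
undo_changed_modification_mass_delta=[Ündô: Chàngéd {0} frôm {1} tô {2}]
undo_changed_modification_name=[Ündô: Chàngéd {0} frôm {1} tô {2}]
undo_changed_modifications=[Ündô: Chàngéd môdïfïcàtïôns {0}]
undo_changed_modifications_static_mods=[Ündô: Chàngéd stàtïc môds ({0})]
undo_changed_modifications_variable_mods=[Ündô: Chàngéd vàrïàblé môds ({0})]
undo_changed_peptide=[Ündô: Chàngéd péptïdé {0}]
undo_changed_peptide_precursors=[Ündô: Chàngéd précürsôrs ({0})]
undo_changed_peptide_sequence=[Ündô: Chàngéd {0} frôm {1} tô {2}]
undo_changed_peptide_settings=[Ündô: Chàngéd péptïdé séttïngs {0}]
undo_changed_peptide_settings_digestion=[Ündô: Chàngéd dïgéstïôn ({0})]
undo_changed_peptide_settings_modifications=[Ündô: Chàngéd môdïfïcàtïôns ({0})]
undo_changed_precursor=[Ündô: Chàngéd précürsôr {0}]
undo_changed_precursor_charge=[Ündô: Chàngéd {0} frôm {1} tô {2}]
undo_changed_precursor_transitions=[Ündô: Chàngéd trànsïtïôns ({0})]
undo_changed_protein=[Ündô: Chàngéd prôtéïn {0}]
undo_changed_protein_name=[Ündô: Chàngéd {0} frôm {1} tô {2}]
undo_changed_protein_peptides=[Ündô: Chàngéd péptïdés ({0})]
undo_changed_settings=[Ündô: Chàngéd séttïngs {0}]
undo_changed_settings_peptide_settings=[Ündô: Chàngéd péptïdé séttïngs ({0})]
undo_changed_settings_transition_settings=[Ündô: Chàngéd trànsïtïôn séttïngs ({0})]
undo_changed_transition=[Ündô: Chàngéd trànsïtïôn {0}]
undo_changed_transition_fragment_ion=[Ündô: Chàngéd {0} frôm {1} tô {2}]
undo_changed_transition_product_charge=[Ündô: Chàngéd {0} frôm {1} tô {2}]
undo_changed_transition_settings=[Ündô: Chàngéd trànsïtïôn séttïngs {0}]
undo_changed_transition_settings_filter=[Ündô: Chàngéd fïltér ({0})]
undo_changed_transition_settings_full_scan=[Ündô: Chàngéd füll scàn ({0})]
undo_changed_transition_settings_instrument=[Ündô: Chàngéd ïnstrümént ({0})]
undo_document_created=[Ündô: Dôcümént créàtéd]
undo_removed_modification=[Ündô: Rémôvéd môdïfïcàtïôn {0}]
undo_removed_peptide=[Ündô: Rémôvéd péptïdé {0}]
undo_removed_precursor=[Ündô: Rémôvéd précürsôr {0}]
undo_removed_protein=[Ündô: Rémôvéd prôtéïn {0}]
undo_removed_transition=[Ündô: Rémôvéd trànsïtïôn {0}]
undo_to=[Ündïd àll chàngés bàck thrôügh éntry {0}]
undo_undo_to=[Ündô: Ündïd àll chàngés bàck thrôügh éntry {0}]
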