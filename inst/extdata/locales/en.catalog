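added_modification=Added modification {0}
added_peptide=Added peptide {0}
added_precursor=Added precursor {0}
added_protein=Added protein {0}
added_transition=Added transition {0}
audit_log_disabled=Audit logging disabled
audit_log_enabled=Audit logging enabled
changed_digestion=Changed digestion {0}
changed_digestion_enzyme=Changed {0} from {1} to {2}
changed_digestion_max_missed_cleavages=Changed {0} from {1} to {2}
changed_document=Changed document {0}
changed_document_settings=Changed settings ({0})
changed_document_targets=Changed targets ({0})
changed_filter=Changed filter {0}
changed_filter_ion_types=Changed {0} from {1} to {2}
changed_filter_max_mz=Changed {0} from {1} to {2}
changed_filter_min_mz=Changed {0} from {1} to {2}
changed_filter_precursor_charges=Changed {0} from {1} to {2}
changed_full_scan=Changed full scan {0}
changed_full_scan_acquisition_method=Changed {0} from {1} to {2}
changed_full_scan_resolving_power=Changed {0} from {1} to {2}
changed_instrument=Changed instrument {0}
changed_instrument_dynamic_min=Changed {0} from {1} to {2}
changed_instrument_max_mz=Changed {0} from {1} to {2}
changed_instrument_min_mz=Changed {0} from {1} to {2}
changed_modification=Changed modification {0}
changed_modification_mass_delta=Changed {0} from {1} to {2}
changed_modification_name=Changed {0} from {1} to {2}
changed_modifications=Changed modifications {0}
changed_modifications_static_mods=Changed static mods ({0})
changed_modifications_variable_mods=Changed variable mods ({0})
changed_peptide=Changed peptide {0}
changed_peptide_precursors=Changed precursors ({0})
changed_peptide_sequence=Changed {0} from {1} to {2}
changed_peptide_settings=Changed peptide settings {0}
changed_peptide_settings_digestion=Changed digestion ({0})
changed_peptide_settings_modifications=Changed modifications ({0})
changed_precursor=Changed precursor {0}
changed_precursor_charge=Changed {0} from {1} to {2}
changed_precursor_transitions=Changed transitions ({0})
changed_protein=Changed protein {0}
changed_protein_name=Changed {0} from {1} to {2}
changed_protein_peptides=Changed peptides ({0})
changed_settings=Changed settings {0}
changed_settings_peptide_settings=Changed peptide settings ({0})
changed_settings_transition_settings=Changed transition settings ({0})
changed_transition=Changed transition {0}
changed_transition_fragment_ion=Changed {0} from {1} to {2}
changed_transition_product_charge=Changed {0} from {1} to {2}
changed_transition_settings=Changed transition settings {0}
changed_transition_settings_filter=Changed filter ({0})
changed_transition_settings_full_scan=Changed full scan ({0})
changed_transition_settings_instrument=Changed instrument ({0})
document_created=Document created
removed_modification=Removed modification {0}
removed_peptide=Removed peptide {0}
removed_precursor=Removed precursor {0}
removed_protein=Removed protein {0}
removed_transition=Removed transition {0}
undo_added_modification=Undo: Added modification {0}
undo_added_peptide=Undo: Added peptide {0}
undo_added_precursor=Undo: Added precursor {0}
undo_added_protein=Undo: Added protein {0}
undo_added_transition=Undo: Added transition {0}
undo_audit_log_disabled=Undo: Audit logging disabled
undo_audit_log_enabled=Undo: Audit logging enabled
undo_changed_digestion=Undo: Changed digestion {0}
undo_changed_digestion_enzyme=Undo: Changed {0} from {1} to {2}
undo_changed_digestion_max_missed_cleavages=Undo: Changed {0} from {1} to {2}
undo_changed_document=Undo: Changed document {0}
undo_changed_document_settings=Undo: Changed settings ({0})
undo_changed_document_targets=Undo: Changed targets ({0})
undo_changed_filter=Undo: Changed filter {0}
undo_changed_filter_ion_types=Undo: Changed {0} from {1} to {2}
undo_changed_filter_max_mz=Undo: Changed {0} from {1} to {2}
undo_changed_filter_min_mz=Undo: Changed {0} from {1} to {2}
undo_changed_filter_precursor_charges=Undo: Changed {0} from {1} to {2}
undo_changed_full_scan=Undo: Changed full scan {0}
undo_changed_full_scan_acquisition_method=Undo: Changed {0} from {1} to {2}
undo_changed_full_scan_resolving_power=Undo: Changed {0} from {1} to {2}
undo_changed_instrument=Undo: Changed instrument {0}
undo_changed_instrument_dynamic_min=Undo: Changed {0} from {1} to {2}
undo_changed_instrument_max_mz=Undo: Changed {0} from {1} to {2}
undo_changed_instrument_min_mz=Undo: Changed {0} from {1} to {2}
undo_changed_modification=Undo: Changed modification {0}
undo_changed_modification_mass_delta=Undo: Changed {0} from {1} to {2}
undo_changed_modification_name=Undo: Changed {0} from {1} to {2}
undo_changed_modifications=Undo: Changed modifications {0}
undo_changed_modifications_static_mods=Undo: Changed static mods ({0})
undo_changed_modifications_variable_mods=Undo: Changed variable mods ({0})
undo_changed_peptide=Undo: Changed peptide {0}
undo_changed_peptide_precursors=Undo: Changed precursors ({0})
undo_changed_peptide_sequence=Undo: Changed {0} from {1} to {2}
undo_changed_peptide_settings=Undo: Changed peptide settings {0}
undo_changed_peptide_settings_digestion=Undo: Changed digestion ({0})
undo_changed_peptide_settings_modifications=Undo: Changed modifications ({0})
undo_changed_precursor=Undo: Changed precursor {0}
undo_changed_precursor_charge=Undo: Changed {0} from {1} to {2}
undo_changed_precursor_transitions=Undo: Changed transitions ({0})
undo_changed_protein=Undo: Changed protein {0}
undo_changed_protein_name=Undo: Changed {0} from {1} to {2}
undo_changed_protein_peptides=Undo: Changed peptides ({0})
undo_changed_settings=Undo: Changed settings {0}
undo_changed_settings_peptide_settings=Undo: Changed peptide settings ({0})
undo_changed_settings_transition_settings=Undo: Changed transition settings ({0})
undo_changed_transition=Undo: Changed transition {0}
undo_changed_transition_fragment_ion=Undo: Changed {0} from {1} to {2}
undo_changed_transition_product_charge=Undo: Changed {0} from {1} to {2}
undo_changed_transition_settings=Undo: Changed transition settings {0}
undo_changed_transition_settings_filter=Undo: Changed filter ({0})
undo_changed_transition_settings_full_scan=Undo: Changed full scan ({0})
undo_changed_transition_settings_instrument=Undo: Changed instrument ({0})
undo_document_created=Undo: Document created
undo_removed_modification=Undo: Removed modification {0}
undo_removed_peptide=Undo: Removed peptide {0}
undo_removed_precursor=Undo: Removed precursor {0}
undo_removed_protein=Undo: Removed protein {0}
undo_removed_transition=Undo: Removed transition {0}
undo_to=Undid all changes back through entry {0}
undo_undo_to=Undo: Undid all changes back through entry {0}
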