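# Candidate values for the synthetic document and edit-sequence generator.
# Pools are small and fixed so generated documents, canonical bytes and
# hashes are reproducible from a seed alone. Numeric pools use at most four
# decimal places.
filter:
  precursor_charges: [[2], [2, 3], [2, 3, 4], [1, 2]]
  ion_types: [["y"], ["b"], ["y", "b"], ["y", "b", "a"]]
  min_mz: [50, 60, 100, 150, 300]
  max_mz: [1000, 1200, 1500, 1800, 2000]
instrument:
  min_mz: [50, 100, 200]
  max_mz: [1500, 1800, 2000, 2500]
  dynamic_min: [true, false]
full_scan:
  acquisition_method: [none, targeted, dia]
  resolving_power: [10000, 30000, 60000, 120000]
digestion:
  enzyme: [trypsin, lysc, argc, chymotrypsin]
  max_missed_cleavages: [0, 1, 2]
modification:
  name: [carbamidomethyl_c, oxidation_m, phospho_sty, acetyl_n, label_13c6]
  mass_delta: [57.0215, 15.9949, 79.9663, 42.0106, 6.0201]
protein:
  name: [P01, P02, P03, P04, P05, P06, P07, P08]
peptide:
  alphabet: [A, C, D, E, F, G, H, I, K, L, M, N, P, Q, R, S, T, V, W, Y]
precursor:
  charge: [1, 2, 3, 4]
transition:
  fragment_ion: [y1, y2, y3, y4, y5, b1, b2, b3, b4, b5]
  product_charge: [1, 2]
usernames: [alice, bob, carol]
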