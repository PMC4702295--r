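# Demo pipeline configuration: simulate a small superfamily with planted
# subgroup patterns, then run every downstream stage on it.
seed: 11
stages: [simulate, align, cluster, bpps, cha, tree, classify]
simulate:
  n_groups: 4
  seqs_per_group: 12
  core_length: 60
  patterns_per_group: 5
  fg_match_prob: 0.95
  bg_match_prob: 0.05
align:
  n_rounds: 2
  threshold: 25
cluster:
  threshold: 0.60
bpps:
  n_sweeps: 15
  burn_in: 8
  seeds_per_group: 3
  rho: 0.2
cha:
  display_rows: 2
tree:
  n_reps: 20
classify:
  cat_loop: [23, 24, 25, 26, 27, 28]
  dfg_region: [40, 41, 42, 43]
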