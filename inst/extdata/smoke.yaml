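# Small synthetic-study configuration exercising the full pipeline:
# two populations, both chromosome classes, hemizygous females, DP/GQ
# emulation straddling the filters, and closed-form truth at m = 0.
seed: 7
out_dir: zdiv_smoke
synth:
  n_populations: 2
  n_individuals: 5
  female_fraction: 0.4
  Ne: 1.0e+06
  split_time: 1.0e+06
  migration: 0
  n_windows_autosome: 60
  n_windows_z: 40
  locus_length: 5000
  missingness: 0.02
ratios:
  n_permutations: 199
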