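# Example run configuration for `phenoflux run-all --config ... --out ...`.
# Any field omitted here falls back to the package default (see
# ?default_config); `seed` is required and drives every stage substream.
seed: 42
sites:
  n_sites: 10
  n_years: 12
  start_year: 2005
phenology:
  base_sos: 120
  true_st: -2.0
  sos_noise_sd: 3.0
qc:
  mad_k: 2.5
  ndvi_threshold: 0.1
  min_years: 5
rf:
  ntree: 1000
  mtry: 4
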