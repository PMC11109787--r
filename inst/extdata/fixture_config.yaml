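# Packaged synthetic fixture: 200 variants, two mechanism clusters plus
# null and junk fractions, three secondary traits, one independent
# validation outcome. All data are generated at run time from this config.
simulate:
  n_variants: 200
  cluster_slopes: [0.4, -0.6]
  cluster_weights: [0.35, 0.25]
  null_frac: 0.3
  junk_frac: 0.1
  pleiotropy_sd: 0.05
  exposure_effect_mean: 0.05
  n_exposure: 50000
  n_outcome: 50000
  n_validation: 100000
  trait_n: 100000
  palindromic_frac: 0.1
  trait_signatures:
    - {glucose: 0.2, lipids: -0.1, crp: 0.0}
    - {glucose: -0.3, lipids: 0.1, crp: 0.0}
clustering:
  K_max: 4
  threshold: 0.8
  n_restarts: 5
mr:
  n_boot: 500
profiling:
  method: DL
seed: 7
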