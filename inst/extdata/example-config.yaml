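# Example pipeline configuration covering all stages.
# Usage:
#   Rscript inst/cli/bruvshealth simulate --config example-config.yaml --out-dir out
simulate:
  design: study            # the default 5-site, 108-deployment layout
  parameters: default      # default_generative_parameters()
fit:
  n_chains: 4
  draws: 10000
  warmup: 500
  adapt: 500
assess:
  baseline_year: 2018
  categories:
    names: [poor, fair, good, very_good]
    lower: [0, 0.5, 0.7, 0.9]
power:
  rho: [0.05, 0.25, 0.5, 0.7, 0.9, 1]
  alpha: [5, 10, 20]
  n_replicates: 500
  parameters: default
  baseline_deviation: neutral
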