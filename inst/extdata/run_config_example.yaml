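# Example run configuration: overrides merge over default_config().
# The shipped rate schedule and all generator outputs are synthetic.
seed: 1
synthetic:
  n_x: 32
  n_y: 32
  n_days: 365
  n_sites: 80
scenario:
  delta: 0.1
prep:
  smote:
    multiplier: 1.0
burden:
  base_vsl: 9.0e6
  base_year: 2013
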