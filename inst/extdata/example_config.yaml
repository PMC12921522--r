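# Example run configuration. "default" and "synthetic" resolve to the
# shipped generators; replace them with file paths to use your own
# parameter ledger or life table.
ledger: default
life_table: synthetic
calibrate: true
settings:
  horizon_years: 15
  discount_rate: 0.03
  wtp: 50000
  n_sims: 10000
  seed: 1
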