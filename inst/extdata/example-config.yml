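# Example pipeline configuration: a small cohort for a quick end-to-end run.
seed: 7
task:
  n_blocks: 3
  trials_per_condition: 30
  p_high: 0.70
  p_low: 0.30
  reversal_period: 10
cohort:
  n_obs: 12
  n_con: 12
  p_selfish: 0.64
  missing_rate: 0.01
fit:
  tau_max: 20
  v0: 0.5
analysis:
  n_sims: 200
  grid_n_sims: 200
  n_boot: 500
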