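model:
  a_min: 0.002
  a_max: 1.0
  r: 2.2
  d: 1.02
  tau_c: 24.0
  dt: 1.0
  f_alpha:
  - 0.05
  - 0.5
  - 18.0
  - 0.0005
  f_omega:
  - 0.02
  - 0.5
  - 6.0
  - 0.002
  N_bar_A: 2000.0
  N_bar_Omega: 2000.0
  alpha_mult:
    host: 1.0
    bulk: 3.0
    A: 3.0
    B: 3.0
  omega_mult:
    host: 1.0
    bulk: 1500.0
    A: 1500.0
    B: 1500.0
  death_rate:
    host: 0.0
    bulk: 0.0
    A: 0.0
    B: 0.0
  pool_scale: 1.0
engraftment:
  mean_bulk: 1.0e-06
  ab_shift: 0.02
  concentration: 1.0
  window_hours: 48.0
criterion:
  threshold: 0.2
horizon_days: 25.0
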