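model:
  'N': 2000
  p_conn: 0.05
  p_exc: 0.8
  p_inh: 0.2
  eps_exc: 0.01
  eps_inh: -0.035
  gamma: 1.0
  I_ext: 1.25
  V_theta: 1.0
  V_reset: 0.0
  tau: 0.1
modulation:
  theta_b: .inf
  theta_s: .inf
  s_sat: .inf
  linear: yes
protocol:
  t_pre: 50.0
  K_obs: 50.0
  t_post: 20.0
  g0: 100.0
  stim_mode: random
analysis:
  f_max: 0.1
  K_min: 20.0
seed: 1
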