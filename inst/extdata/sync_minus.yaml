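neuron:
  C: 0.25
  g_rest: 25.0
  E_e: 0.0
  E_i: -85.0
  E_rest: -65.0
  V_th: -50.0
  tau_s: 5.0
  syn_delay: 10.0
  ie_delay: 5.0
  dt: 0.1
  sigma_noise: 2.8
  A_E: 3.5
  A_I: 6.6
  n_syn: 10.0
  jitter_syn: 1.0
plasticity:
  mode: depression
  A_DE: 0.4
  A_DI: 0.1
  tau_pE: 0.15
  tau_pI: 0.1
  P0_E: 1.0
  P0_I: 1.0
  delta_g_sra: 0.0
  tau_sra: 50.0
  E_K: -85.0
stimulus:
  rates:
  - 4.0
  - 8.0
  - 12.0
  - 16.0
  - 20.0
  - 24.0
  - 28.0
  - 32.0
  - 36.0
  - 40.0
  - 44.0
  - 48.0
  duration: 500.0
  pre: 500.0
  post: 500.0
  jitter_sd: 0.0
experiment:
  type: neuron
  trials: 10
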