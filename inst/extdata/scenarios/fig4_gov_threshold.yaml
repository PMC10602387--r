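name: fig4_gov_threshold
mode: government
epidemic: {kappa_star: 4.0, i0: 3.0e-8}
utility:
  f: 1.0
  beta: 1.0
  cost: {alpha0: 100.0, alpha1: 400.0, i_hc: 0.01, sigma: 300.0}
government:
  f_g: 1.0
  beta_g: 1.0
  gamma_g: 0.5
  cost: {alpha0: 100.0, alpha1: 400.0, i_hc: 0.01, sigma: 300.0}
grid: {tf: 100, n: 5001}
sweep: {relaxation: 0.1, max_iter: 20000}
sweep_outer: {relaxation: 0.05, max_iter: 20000}
seed: 1
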