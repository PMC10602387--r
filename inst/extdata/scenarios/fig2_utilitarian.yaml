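name: fig2_utilitarian
mode: utilitarian
epidemic: {kappa_star: 4.0, i0: 3.0e-8}
utility:
  f: 1.0
  beta: 1.0
  cost: {constant: true, alpha0: 400.0}
grid: {tf: 100, n: 5001}
sweep: {relaxation: 0.1, max_iter: 20000}
seed: 1
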