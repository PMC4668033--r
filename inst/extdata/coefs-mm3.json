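{
  "description": "Kozak (2004) taper equation for maritime pine in Asturias, two-level mixed-effects fit (random effects in a1 and b3 at plot and tree level, power-of-DBH variance function), REML, whole 420-tree dataset",
  "a0": 1.050,
  "a1": 0.9427,
  "a2": 0.04734,
  "b1": 0.3619,
  "b2": -0.6907,
  "b3": 0.5847,
  "b4": 1.126,
  "b5": 0.02271,
  "b6": -0.05812,
  "random": ["a1", "b3"],
  "D_plot.a1.a1": 1.263e-5,
  "D_plot.b3.b3": 8.273e-4,
  "D_plot.a1.b3": -1.104e-5,
  "D_tree.a1.a1": 1.205e-4,
  "D_tree.b3.b3": 3.095e-3,
  "D_tree.a1.b3": 3.847e-5,
  "sigma2": 6.117e-3,
  "delta": 0.7405
}
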