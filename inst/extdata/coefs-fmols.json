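{
  "description": "Kozak (2004) taper equation for maritime pine in Asturias, fixed-effects fit by nonlinear OLS on the whole 420-tree dataset",
  "a0": 0.9891,
  "a1": 0.9633,
  "a2": 0.04585,
  "b1": 0.3672,
  "b2": -0.3350,
  "b3": 0.5192,
  "b4": 0.8471,
  "b5": 0.01777,
  "b6": -0.02647,
  "sigma2": 1.555
}
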