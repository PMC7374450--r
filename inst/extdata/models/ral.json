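{
  "phase": "RAL",
  "validity_deg": [0, 150],
  "axes": {
    "x": {"kind": "polynomial", "coefficients": [-3.749e-08, 7.817e-06, -2.005e-03, -0.004244]},
    "y": {"kind": "polynomial", "coefficients": [2.487e-08, -4.634e-06, -1.046e-03, 0.001629]},
    "z": {"kind": "polynomial", "coefficients": [-1.091e-07, 2.518e-05, 1.122e-03, 0.005731]}
  }
}
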