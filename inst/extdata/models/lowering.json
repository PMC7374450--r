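{
  "phase": "lowering",
  "validity_deg": [0, 150],
  "axes": {
    "x": {"kind": "polynomial", "coefficients": [-6.219e-08, 1.577e-05, -0.002594, -0.006606]},
    "y": {"kind": "polynomial", "coefficients": [-4.927e-08, 1.482e-05, -0.002399, 0.002663]},
    "z": {"kind": "polynomial", "coefficients": [1.81e-09, -6.903e-07, 8.636e-05, -1.304e-03, 0.002328]}
  }
}
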