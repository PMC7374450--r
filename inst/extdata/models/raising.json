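{
  "phase": "raising",
  "validity_deg": [0, 150],
  "axes": {
    "x": {"kind": "polynomial", "coefficients": [-1.279e-08, -1.404e-07, -1.416e-03, -0.001883]},
    "y": {"kind": "polynomial", "coefficients": [-1.095e-09, 4.275e-07, -5.57e-05, 1.352e-03, -0.009944]},
    "z": {"kind": "polynomial", "coefficients": [-7.088e-08, 1.623e-05, 1.819e-03, 0.007573]}
  }
}
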