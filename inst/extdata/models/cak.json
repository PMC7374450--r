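{
  "phase": "CAK",
  "validity_deg": [0, 150],
  "axes": {
    "x": {"kind": "polynomial", "coefficients": [-8.585e-10, 1.783e-07, -1.343e-05, -1.201e-03, -0.002929]},
    "y": {"kind": "rational",
          "numerator": [-7.101e-02, 3.798, -83.28],
          "denominator": [1, -147.4, 7895],
          "offset": -0.001055},
    "z": {"kind": "polynomial", "coefficients": [5.108e-10, -4.124e-07, 7.918e-05, -1.714e-03, 0.001467]},
    "d": {"kind": "polynomial", "coefficients": [7.435e-10, -4.161e-07, 7.25e-05, -6.134e-04, 0.002263]}
  }
}
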