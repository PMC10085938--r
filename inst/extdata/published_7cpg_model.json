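{
  "intercept": -1.588,
  "coefficients": {
    "PDE4C": -0.04,
    "EDARADD": -1.912,
    "KLF14": 5.0157,
    "ELOVL2": 0.5961,
    "FHL2": 1.7463,
    "C1orf132": -0.0108,
    "TRIM59": 3.5634
  },
  "residual_standard_error": 0.2905,
  "cutoff": 20,
  "sex_scope": "unisex",
  "n_train": 161,
  "df_residual": 153
}
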