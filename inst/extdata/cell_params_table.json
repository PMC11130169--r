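[
  {
    "cell_line": "WI-38",
    "k_N": 38.4,
    "a": 5.59e-3,
    "b": 8.17e-6,
    "a_plus_c": 0.371,
    "alpha0": 0.590,
    "beta0": 1.63e-2,
    "gamma": 0.954,
    "sd": {
      "k_N": 1.70,
      "a": 1.20e-3,
      "b": 6.73e-6,
      "a_plus_c": 3.84e-2,
      "alpha0": 1.07e-1,
      "beta0": 1.32e-2
    }
  },
  {
    "cell_line": "HLEC",
    "k_N": 40.6,
    "a": 4.27e-3,
    "b": 6.58e-6,
    "a_plus_c": 0.309,
    "alpha0": 0.559,
    "beta0": 1.75e-2,
    "gamma": 0.954,
    "sd": {
      "k_N": 2.63,
      "a": 1.07e-3,
      "b": 4.90e-6,
      "a_plus_c": 5.58e-2,
      "alpha0": 9.51e-2,
      "beta0": 1.24e-2
    }
  }
]
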