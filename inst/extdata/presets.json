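{
  "rat_room": {
    "SE": {
      "ru": {
        "Q": 3,
        "mu": 10,
        "gamma": 20,
        "kd_bar": 1.622,
        "alpha_kd": 0,
        "SL_kd": 2.15,
        "koff": 120,
        "kbasic": 28,
        "kd_floor_frac": 0.05
      },
      "xb": {
        "mu_fP0": 57.416,
        "mu_fP1": 1.368,
        "r0": 134.31,
        "alpha": 25.184,
        "a_XB": 22.894
      }
    },
    "MF": {
      "ru": {
        "Q": 2,
        "mu": 10,
        "gamma": 12,
        "kd_bar": 0.835,
        "alpha_kd": -1.258,
        "SL_kd": 2.15,
        "koff": 120,
        "kbasic": 24,
        "kd_floor_frac": 0.05
      },
      "xb": {
        "mu_fP0": 32.708,
        "mu_fP1": 0.779,
        "r0": 134.31,
        "alpha": 25.184,
        "a_XB": 22.894
      }
    }
  },
  "human_body": {
    "SE": {
      "ru": {
        "Q": 3,
        "mu": 10,
        "gamma": 20,
        "kd_bar": 0.74,
        "alpha_kd": 0,
        "SL_kd": 2.15,
        "koff": 100,
        "kbasic": 13,
        "kd_floor_frac": 0.05
      },
      "xb": {
        "mu_fP0": 57.157,
        "mu_fP1": 1.362,
        "r0": 134.31,
        "alpha": 25.184,
        "a_XB": 22.894
      }
    },
    "MF": {
      "ru": {
        "Q": 2,
        "mu": 10,
        "gamma": 12,
        "kd_bar": 0.381,
        "alpha_kd": -0.571,
        "SL_kd": 2.15,
        "koff": 100,
        "kbasic": 13,
        "kd_floor_frac": 0.05
      },
      "xb": {
        "mu_fP0": 32.653,
        "mu_fP1": 0.778,
        "r0": 134.31,
        "alpha": 25.184,
        "a_XB": 22.894
      }
    }
  },
  "geometry": {
    "SL0": 2.2,
    "LA": 1.25,
    "LM": 1.65,
    "LH": 0.18,
    "eps": 0.05,
    "n_ru": 32,
    "n_mh": 18,
    "DM": 0.0408333333333333
  }
}
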