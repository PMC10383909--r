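{
  "schema": "qspr-model-bank/1",
  "note": "Published GA-MLR equations for metal-ligand stability constants (logB, log10 units) and potentiometric sensitivity (PS, mV/dec). Coefficients apply to descriptors in standard-scaled (training-statistics) space.",
  "models": {
    "Cd_logB": {
      "metal": "Cd2+", "property": "logB", "intercept": 9.2894,
      "terms": {
        "RBN": -2.6191, "SPI": 6.0044, "H_D/Dt": 15.7303,
        "MATS1m": -4.6761, "MATS2m": -11.3909, "MATS6i": 4.987
      }
    },
    "Cu_logB": {
      "metal": "Cu2+", "property": "logB", "intercept": 8.2894,
      "terms": {
        "nHM": 7.1518, "ATSC4e": 5.5297, "MATS1v": 5.6081,
        "MATS6p": 9.7064, "MATS7p": -10.5641, "GATS5p": 7.4692,
        "P_VSA_MR_7": 12.2912, "SM07_AEAed": -19.6671, "O-057": 8.5756,
        "NssCH2": 12.5774, "B06[C-O]": -1.8575
      }
    },
    "Pb_logB": {
      "metal": "Pb2+", "property": "logB", "intercept": 4.6561,
      "terms": {
        "nR05": -1.1628, "J_Dt": -6.1855, "ATSC1s": 6.4076,
        "GATS8m": 6.4211, "SM03_EAbo": -6.0816
      }
    },
    "Cd_PS": {
      "metal": "Cd2+", "property": "PS", "intercept": -32.5684,
      "terms": {
        "J_Bs": -13.696, "GATS8i": 16.1241, "JGI8": 27.1608,
        "SpMax4_Bhm": 30.3906, "SpMin3_Bhs": -21.3087,
        "SpMin5_Bhs": 38.7644, "DLS_01": 9.2121
      }
    },
    "Cu_PS": {
      "metal": "Cu2+", "property": "PS", "intercept": 35.4214,
      "terms": {
        "Ho_Dzp": -16.7676, "GGI10": -12.1368, "P_VSA_p_2": -29.2904,
        "Chi1_EAdm": 23.0366, "DLS_04": 17.6022, "LLS_01": -42.4502
      }
    },
    "Pb_PS": {
      "metal": "Pb2+", "property": "PS", "intercept": -53.7619,
      "terms": {
        "MATS6v": 16.311, "MATS2i": 30.6395, "GATS4i": -10.6447,
        "GGI8": -50.3016, "JGI8": 45.0039, "SpMin5_Bhs": 71.9904,
        "Eta_F_A": 24.299
      }
    }
  }
}
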