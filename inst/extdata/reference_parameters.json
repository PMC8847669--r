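{
  "mu_BS": {
    "value": 0.015,
    "lower": 0.0001,
    "upper": 100,
    "unit": "1/h",
    "fixed": false,
    "group": "distribution"
  },
  "mu_BLu": {
    "value": 0.3,
    "lower": 0.0001,
    "upper": 100,
    "unit": "1/h",
    "fixed": false,
    "group": "distribution"
  },
  "mu_BLi": {
    "value": 0.25,
    "lower": 0.0001,
    "upper": 100,
    "unit": "1/h",
    "fixed": false,
    "group": "distribution"
  },
  "mu": {
    "value": 0.1,
    "lower": 0.0001,
    "upper": 100,
    "unit": "1/h",
    "fixed": false,
    "group": "distribution"
  },
  "mu_S0": {
    "value": 0.02,
    "lower": 0.0001,
    "upper": 100,
    "unit": "1/h",
    "fixed": false,
    "group": "distribution"
  },
  "mu_Lu0": {
    "value": 0.15,
    "lower": 0.0001,
    "upper": 100,
    "unit": "1/h",
    "fixed": false,
    "group": "distribution"
  },
  "Q_Blood": {
    "value": 5000000,
    "lower": 5000000,
    "upper": 5000000,
    "unit": "mm3",
    "fixed": true,
    "group": "distribution"
  },
  "Q_Spleen": {
    "value": 100000,
    "lower": 100000,
    "upper": 100000,
    "unit": "mm3",
    "fixed": true,
    "group": "distribution"
  },
  "Q_Lung": {
    "value": 1300000,
    "lower": 1300000,
    "upper": 1300000,
    "unit": "mm3",
    "fixed": true,
    "group": "distribution"
  },
  "Q_Liver": {
    "value": 1500000,
    "lower": 1500000,
    "upper": 1500000,
    "unit": "mm3",
    "fixed": true,
    "group": "distribution"
  },
  "k_ph1_TRAF2": {
    "value": 1.5,
    "lower": 0.0001,
    "upper": 100,
    "unit": "1/h",
    "fixed": false,
    "group": "signaling"
  },
  "k_ph1_IRAK1": {
    "value": 1.2,
    "lower": 0.0001,
    "upper": 100,
    "unit": "1/h",
    "fixed": false,
    "group": "signaling"
  },
  "k_ph2": {
    "value": 0.5,
    "lower": 0.0001,
    "upper": 100,
    "unit": "1",
    "fixed": false,
    "group": "signaling"
  },
  "k_deg_TRAF2p": {
    "value": 2,
    "lower": 0.0001,
    "upper": 100,
    "unit": "1/h",
    "fixed": false,
    "group": "signaling"
  },
  "k_deg_IRAK1p": {
    "value": 2,
    "lower": 0.0001,
    "upper": 100,
    "unit": "1/h",
    "fixed": false,
    "group": "signaling"
  },
  "k_syn_IKK": {
    "value": 0.06,
    "lower": 0.0001,
    "upper": 100,
    "unit": "1/h",
    "fixed": false,
    "group": "signaling"
  },
  "k_act_IKK": {
    "value": 0.6,
    "lower": 0.0001,
    "upper": 100,
    "unit": "1/h",
    "fixed": false,
    "group": "signaling"
  },
  "k_deg_IKK": {
    "value": 0.06,
    "lower": 0.0001,
    "upper": 100,
    "unit": "1/h",
    "fixed": false,
    "group": "signaling"
  },
  "k_deg_IKKb": {
    "value": 0.84,
    "lower": 0.0001,
    "upper": 100,
    "unit": "1/h",
    "fixed": false,
    "group": "signaling"
  },
  "N_tot": {
    "value": 1,
    "lower": 0.0001,
    "upper": 10,
    "unit": "1",
    "fixed": false,
    "group": "nfkb"
  },
  "k_ass": {
    "value": 184,
    "lower": 0.0001,
    "upper": 10000,
    "unit": "1/h",
    "fixed": false,
    "group": "nfkb"
  },
  "k_transc_mIkBa": {
    "value": 280,
    "lower": 0.0001,
    "upper": 10000,
    "unit": "1/h",
    "fixed": false,
    "group": "nfkb"
  },
  "k_deg_mIkBa": {
    "value": 12,
    "lower": 0.0001,
    "upper": 1000,
    "unit": "1/h",
    "fixed": false,
    "group": "nfkb"
  },
  "k_tranl_IkBa": {
    "value": 280,
    "lower": 0.0001,
    "upper": 10000,
    "unit": "1/h",
    "fixed": false,
    "group": "nfkb"
  },
  "k_loss_IkBa": {
    "value": 300,
    "lower": 0.0001,
    "upper": 10000,
    "unit": "1/h",
    "fixed": false,
    "group": "nfkb"
  },
  "k_transc1_mIL8": {
    "value": 0.002,
    "lower": 0.0001,
    "upper": 100,
    "unit": "1/h",
    "fixed": false,
    "group": "cytokine"
  },
  "k_transc2_mIL8": {
    "value": 2,
    "lower": 0.0001,
    "upper": 100,
    "unit": "1/h",
    "fixed": false,
    "group": "cytokine"
  },
  "k_deg_mIL8": {
    "value": 2,
    "lower": 0.0001,
    "upper": 100,
    "unit": "1/h",
    "fixed": false,
    "group": "cytokine"
  },
  "k_transl_IL8": {
    "value": 1,
    "lower": 0.0001,
    "upper": 100,
    "unit": "1/h",
    "fixed": false,
    "group": "cytokine"
  },
  "k_deg_IL8": {
    "value": 1,
    "lower": 0.0001,
    "upper": 100,
    "unit": "1/h",
    "fixed": false,
    "group": "cytokine"
  },
  "k_sec_IL8": {
    "value": 1,
    "lower": 0.0001,
    "upper": 100,
    "unit": "1/h",
    "fixed": false,
    "group": "cytokine"
  },
  "k_transc2_mIL6": {
    "value": 2,
    "lower": 0.0001,
    "upper": 100,
    "unit": "1/h",
    "fixed": false,
    "group": "cytokine"
  },
  "k_deg_mIL6": {
    "value": 2,
    "lower": 0.0001,
    "upper": 100,
    "unit": "1/h",
    "fixed": false,
    "group": "cytokine"
  },
  "k_transl_IL6": {
    "value": 1,
    "lower": 0.0001,
    "upper": 100,
    "unit": "1/h",
    "fixed": false,
    "group": "cytokine"
  },
  "k_deg_IL6": {
    "value": 2,
    "lower": 0.0001,
    "upper": 100,
    "unit": "1/h",
    "fixed": false,
    "group": "cytokine"
  },
  "k_transc2_mIL12": {
    "value": 2,
    "lower": 0.0001,
    "upper": 100,
    "unit": "1/h",
    "fixed": false,
    "group": "cytokine"
  },
  "k_deg_mIL12": {
    "value": 2,
    "lower": 0.0001,
    "upper": 100,
    "unit": "1/h",
    "fixed": false,
    "group": "cytokine"
  },
  "k_transl_IL12": {
    "value": 1,
    "lower": 0.0001,
    "upper": 100,
    "unit": "1/h",
    "fixed": false,
    "group": "cytokine"
  },
  "k_deg_IL12": {
    "value": 2,
    "lower": 0.0001,
    "upper": 100,
    "unit": "1/h",
    "fixed": false,
    "group": "cytokine"
  },
  "k_transc2_CD70": {
    "value": 2,
    "lower": 0.0001,
    "upper": 100,
    "unit": "1/h",
    "fixed": false,
    "group": "cytokine"
  },
  "k_deg_CD70": {
    "value": 2,
    "lower": 0.0001,
    "upper": 100,
    "unit": "1/h",
    "fixed": false,
    "group": "cytokine"
  },
  "k_act_N": {
    "value": 0.05,
    "lower": 0.0001,
    "upper": 100,
    "unit": "1/h",
    "fixed": false,
    "group": "tcell"
  },
  "K_4": {
    "value": 20000,
    "lower": 1,
    "upper": 100000000,
    "unit": "signal",
    "fixed": false,
    "group": "tcell"
  },
  "k_diff1_EE": {
    "value": 0.04,
    "lower": 0.0001,
    "upper": 100,
    "unit": "1/h",
    "fixed": false,
    "group": "tcell"
  },
  "k_diff2_EE": {
    "value": 0.008,
    "lower": 0.0001,
    "upper": 100,
    "unit": "1/h",
    "fixed": false,
    "group": "tcell"
  },
  "k_deg_SLE": {
    "value": 0.002,
    "lower": 0.0001,
    "upper": 100,
    "unit": "1/h",
    "fixed": false,
    "group": "tcell"
  }
}
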