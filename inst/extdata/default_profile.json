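{
  "classes": ["benign", "borderline", "primary_invasive", "metastatic"],
  "prevalence": {
    "benign": 0.75,
    "borderline": 0.05,
    "primary_invasive": 0.16,
    "metastatic": 0.04
  },
  "variables": {
    "age": {
      "kind": "continuous",
      "median": [42, 52.5, 58, 59]
    },
    "lesion_diameter": {
      "kind": "continuous",
      "median": [63, 108, 98, 73]
    },
    "solid_diameter": {
      "kind": "continuous",
      "median": [0, 22, 51, 54],
      "zero_prob": [0.6, 0, 0, 0],
      "pos_median": [12, 22, 51, 54]
    },
    "papillation_count": {
      "kind": "ordinal",
      "mean": [0.35, 1.7, 1.43, 0.93],
      "max": 4
    },
    "ascites": {
      "kind": "binary",
      "prop": [0.032, 0.125, 0.504, 0.4]
    },
    "solid_tumor": {
      "kind": "binary",
      "prop": [0.066, 0.075, 0.322, 0.567]
    },
    "irregular_walls": {
      "kind": "binary",
      "prop": [0.336, 0.675, 0.884, 0.833]
    },
    "ovarian_cancer_history": {
      "kind": "binary",
      "prop": [0.009, 0.05, 0.008, 0.1]
    },
    "bilateral": {
      "kind": "binary",
      "prop": [0.176, 0.125, 0.413, 0.333]
    },
    "papillation_flow": {
      "kind": "binary",
      "prop": [0.068, 0.475, 0.43, 0.233]
    },
    "acoustic_shadows": {
      "kind": "binary",
      "prop": [0.13, 0.025, 0, 0.033]
    },
    "unilocular": {
      "kind": "binary",
      "prop": [0.403, 0.025, 0, 0]
    }
  }
}
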