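{
  "description": "Reference contingency tables and marginal counts from a published 103-patient early breast cancer cohort treated with neoadjuvant chemotherapy. Outcome columns are pCR / no_pCR. Invasive-margin (IM) and ISCR tables are restricted to the 75 patients with an evaluable invasive margin.",
  "tables": {
    "subtype_pcr": {
      "rows": ["luminal", "HER2", "TNBC"],
      "cols": ["pCR", "no_pCR"],
      "counts": [[3, 29], [9, 9], [33, 20]]
    },
    "iscr_tier_pcr": {
      "rows": ["High", "Intermediate", "Low"],
      "cols": ["pCR", "no_pCR"],
      "counts": [[25, 11], [4, 4], [2, 29]]
    },
    "cd3_ct_pcr": {
      "rows": ["high", "low"],
      "cols": ["pCR", "no_pCR"],
      "counts": [[27, 13], [18, 45]]
    },
    "cd8_ct_pcr": {
      "rows": ["high", "low"],
      "cols": ["pCR", "no_pCR"],
      "counts": [[35, 20], [10, 38]]
    },
    "cd3_im_pcr": {
      "rows": ["high", "low"],
      "cols": ["pCR", "no_pCR"],
      "counts": [[29, 17], [2, 27]]
    },
    "cd8_im_pcr": {
      "rows": ["high", "low"],
      "cols": ["pCR", "no_pCR"],
      "counts": [[26, 15], [5, 29]]
    },
    "her2_pcr": {
      "rows": ["positive", "negative"],
      "cols": ["pCR", "no_pCR"],
      "counts": [[9, 9], [36, 49]]
    },
    "tumor_size_pcr": {
      "rows": ["T1", "T2", "T3_4"],
      "cols": ["pCR", "no_pCR"],
      "counts": [[10, 13], [34, 31], [1, 14]]
    },
    "nodal_pcr": {
      "rows": ["positive", "negative"],
      "cols": ["pCR", "no_pCR"],
      "counts": [[19, 35], [24, 21]]
    },
    "stage_pcr": {
      "rows": ["I", "IIA", "IIB", "III"],
      "cols": ["pCR", "no_pCR"],
      "counts": [[6, 3], [25, 24], [11, 15], [3, 16]]
    },
    "er_pcr": {
      "rows": ["positive", "negative"],
      "cols": ["pCR", "no_pCR"],
      "counts": [[8, 37], [37, 21]]
    },
    "pr_pcr": {
      "rows": ["positive", "negative"],
      "cols": ["pCR", "no_pCR"],
      "counts": [[5, 33], [40, 25]]
    },
    "ki67_pcr": {
      "rows": ["ge40", "15_39", "lt15"],
      "cols": ["pCR", "no_pCR"],
      "counts": [[29, 22], [15, 22], [0, 13]]
    },
    "subtype_im_split": {
      "rows": ["with_IM", "without_IM"],
      "cols": ["TNBC", "luminal", "HER2"],
      "counts": [[40, 23, 12], [13, 9, 6]]
    }
  },
  "counts": {
    "iscr_distribution": {
      "labels": ["0", "1", "2", "3", "4"],
      "counts": [27, 4, 8, 13, 23]
    },
    "subtype_total": {
      "labels": ["TNBC", "luminal", "HER2"],
      "counts": [53, 32, 18]
    }
  }
}
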