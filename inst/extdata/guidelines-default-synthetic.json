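{
  "version_label": "synthetic-reconstruction-1 (2004 PBS / 2001 CSANZ vintage)",
  "eligibility": [
    {
      "name": "secondary_prevention",
      "when": [
        "coronary_heart_disease",
        "peripheral_vascular_disease",
        "cerebrovascular_disease",
        "diabetes"
      ],
      "tc_min": 4,
      "ldl_min": null
    },
    {
      "name": "familial",
      "when": [
        "familial_hypercholesterolemia_dx",
        "told_genetic_hypercholesterolemia"
      ],
      "tc_min": 5.5,
      "ldl_min": 4
    },
    {
      "name": "risk_factors",
      "when": [
        "hypertension",
        "current_smoker",
        "family_hx_premature_chd",
        "aboriginal_heritage"
      ],
      "tc_min": 6.5,
      "ldl_min": null
    },
    {
      "name": "general_population",
      "when": [],
      "tc_min": 7.5,
      "ldl_min": null
    }
  ],
  "targets": [
    {
      "name": "high_risk",
      "when": [
        "coronary_heart_disease",
        "peripheral_vascular_disease",
        "cerebrovascular_disease",
        "diabetes"
      ],
      "tc_max": 4,
      "ldl_max": 2.5
    },
    {
      "name": "general",
      "when": [],
      "tc_max": 5.5,
      "ldl_max": 3.5
    }
  ]
}
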