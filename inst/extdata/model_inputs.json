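{
  "description": "Base-case model inputs: transition probabilities, age/sex-banded EQ-5D utilities with Beta parameters, and 2014 GBP costs with Gamma uncertainty where a standard error is available.",
  "discount_rate": 0.035,
  "wtp": 20000,
  "surgical_mortality": { "mean": 0.0050, "se": 0.001 },
  "rerevision_prob": 0.0518,
  "utilities": [
    { "sex": "male", "age_lo": 40, "age_hi": 50, "state": "successful", "mean": 0.736, "se": 0.0179, "alpha": 443, "beta": 159 },
    { "sex": "male", "age_lo": 50, "age_hi": 60, "state": "successful", "mean": 0.767, "se": 0.0066, "alpha": 3133, "beta": 952 },
    { "sex": "male", "age_lo": 60, "age_hi": 70, "state": "successful", "mean": 0.762, "se": 0.0038, "alpha": 9112, "beta": 2393,
      "note": "printed alpha/beta imply mean 0.792, inconsistent with the printed mean 0.762; the loader re-derives the pair from mean/SE by default" },
    { "sex": "male", "age_lo": 0, "age_hi": 200, "state": "revision", "mean": 0.575, "se": 0.009, "alpha": 1496, "beta": 1106 },
    { "sex": "female", "age_lo": 40, "age_hi": 50, "state": "successful", "mean": 0.720, "se": 0.0129, "alpha": 872, "beta": 339 },
    { "sex": "female", "age_lo": 50, "age_hi": 60, "state": "successful", "mean": 0.742, "se": 0.0058, "alpha": 4287, "beta": 1491 },
    { "sex": "female", "age_lo": 60, "age_hi": 70, "state": "successful", "mean": 0.769, "se": 0.0032, "alpha": 13128, "beta": 3944 },
    { "sex": "female", "age_lo": 0, "age_hi": 200, "state": "revision", "mean": 0.553, "se": 0.007, "alpha": 2201, "beta": 1779 }
  ],
  "costs": {
    "RS": {
      "prosthesis": { "mean": 2808 },
      "surgery": { "mean": 1738 },
      "inpatient": { "mean": 1628 },
      "followup_primary": { "mean": 509, "se": 44, "printed_gamma": { "shape": 130, "scale": 4 },
        "note": "printed Gamma pair does not reproduce the mean under shape/scale; moment-matched parameters used" },
      "revision_surgery": { "mean": 16794, "se": 443, "printed_gamma": { "shape": 1435, "scale": 12 },
        "note": "pre-inflation text value 16517; table value used" },
      "followup_postrevision": { "mean": 400, "se": 30, "printed_gamma": { "shape": 169, "scale": 2 },
        "note": "pre-inflation text value 394; table value used" }
    },
    "CeMoP": {
      "prosthesis": { "mean": 1575 },
      "surgery": { "mean": 1738 },
      "inpatient": { "mean": 1687 },
      "followup_primary": { "mean": 400, "se": 30, "printed_gamma": { "shape": 169, "scale": 2 } },
      "revision_surgery": { "mean": 16794, "se": 443, "printed_gamma": { "shape": 1435, "scale": 12 } },
      "followup_postrevision": { "mean": 400, "se": 30, "printed_gamma": { "shape": 169, "scale": 2 } }
    },
    "CeCoP": {
      "prosthesis": { "mean": 2018 },
      "surgery": { "mean": 1738 },
      "inpatient": { "mean": 1687 },
      "followup_primary": { "mean": 400, "se": 30 },
      "revision_surgery": { "mean": 16794, "se": 443 },
      "followup_postrevision": { "mean": 400, "se": 30 }
    },
    "CeLCoC": {
      "prosthesis": { "mean": 3911 },
      "surgery": { "mean": 1738 },
      "inpatient": { "mean": 1687 },
      "followup_primary": { "mean": 400, "se": 30 },
      "revision_surgery": { "mean": 16794, "se": 443 },
      "followup_postrevision": { "mean": 400, "se": 30 }
    }
  },
  "scenarios": {
    "edlin_qaly_gain": null,
    "edlin_note": "placeholder: per-year utility advantage of RS applied for the first two post-surgery years; source table not reproduced in the available text",
    "manufacturer_costs": null,
    "manufacturer_costs_note": "placeholder: device costs as supplied by manufacturers for technology appraisal; source table not reproduced in the available text"
  }
}
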