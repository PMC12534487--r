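{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "affecthmm pipeline report",
  "type": "object",
  "required": [
    "exclusion_report",
    "model_selection",
    "parameters",
    "labeling",
    "dynamics",
    "temporal",
    "descriptives",
    "pca",
    "warnings",
    "provenance"
  ],
  "properties": {
    "exclusion_report": {
      "type": "object",
      "required": ["n_input", "excluded_invalid_code", "excluded_missing",
                   "n_retained", "survivor_fraction"]
    },
    "model_selection": {
      "type": "object",
      "required": ["chosen_K", "bic_table"]
    },
    "parameters": {
      "type": "object",
      "required": ["initial", "transition", "means", "covariance_type",
                   "log_likelihood", "bic"]
    },
    "labeling": {
      "type": "object",
      "required": ["labels", "order", "grand_means"]
    },
    "dynamics": {
      "type": "object",
      "required": ["stationary", "dwell_geometric", "entropy", "entropy_base"]
    },
    "temporal": { "type": "object" },
    "descriptives": { "type": "object", "required": ["overall"] },
    "pca": {
      "type": "object",
      "required": ["explained_variance", "loadings"]
    },
    "provenance": {
      "type": "object",
      "required": ["seed", "package_version", "r_version", "timestamp"]
    }
  }
}
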