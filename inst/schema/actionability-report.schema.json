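{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "$id": "actionability-report.schema.json",
  "title": "Actionability report",
  "type": "object",
  "required": ["schema_version", "diagnosis", "warnings"],
  "properties": {
    "schema_version": { "const": "1.0" },
    "diagnosis": { "$ref": "#/$defs/phase_result" },
    "action": { "$ref": "#/$defs/phase_result" },
    "strata": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["stratum", "n", "mean_delta", "mean_candidate_entropy"],
        "properties": {
          "stratum": { "enum": ["correct", "incorrect"] },
          "n": { "type": "integer", "minimum": 0 },
          "mean_delta": { "$ref": "#/$defs/extended_number" },
          "mean_candidate_entropy": { "$ref": "#/$defs/extended_number" },
          "fraction": { "type": "number", "minimum": 0, "maximum": 1 },
          "n_top1_ties": { "type": "integer", "minimum": 0 }
        }
      }
    },
    "net_benefit": {
      "type": "object",
      "required": ["n", "prevalence", "thresholds", "model_nb", "treat_all_nb", "treat_none_nb"],
      "properties": {
        "note": { "type": "string" },
        "n": { "type": "integer", "minimum": 1 },
        "prevalence": { "type": "number", "minimum": 0, "maximum": 1 },
        "thresholds": { "type": "array", "items": { "type": "number", "exclusiveMinimum": 0, "exclusiveMaximum": 1 } },
        "model_nb": { "type": "array", "items": { "type": "number" } },
        "treat_all_nb": { "type": "array", "items": { "type": "number" } },
        "treat_none_nb": { "type": "array", "items": { "const": 0 } }
      }
    },
    "warnings": { "type": "array", "items": { "type": "string" } }
  },
  "$defs": {
    "extended_number": {
      "description": "IEEE double, with infinities encoded as the strings 'Inf' / '-Inf'",
      "anyOf": [
        { "type": "number" },
        { "enum": ["Inf", "-Inf", "NA", "NaN"] }
      ]
    },
    "phase_result": {
      "type": "object",
      "required": ["phase", "reference", "candidate", "n", "log_base", "mean_delta", "per_sample"],
      "properties": {
        "phase": { "enum": ["diagnosis", "action"] },
        "mode": { "enum": ["self_entropy", "as_printed"] },
        "reference": { "type": "string" },
        "candidate": { "type": "string" },
        "n": { "type": "integer", "minimum": 1 },
        "log_base": { "type": "number", "exclusiveMinimum": 1 },
        "mean_delta": { "$ref": "#/$defs/extended_number" },
        "per_sample": { "type": "array", "items": { "type": "object" } },
        "bootstrap_ci": {
          "type": "object",
          "required": ["low", "high", "n_boot"],
          "properties": {
            "low": { "type": "number" },
            "high": { "type": "number" },
            "n_boot": { "type": "integer", "minimum": 1 }
          }
        },
        "candidate_one_hot_fraction": { "type": "number", "minimum": 0, "maximum": 1 }
      }
    }
  }
}
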