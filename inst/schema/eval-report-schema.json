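{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "semghier evaluation report",
  "type": "object",
  "required": ["schema", "config", "subjects", "aggregate", "wilcoxon", "fsm"],
  "properties": {
    "schema": {"const": "semghier-eval-report/1"},
    "config": {
      "type": "object",
      "required": ["n_subjects", "seed", "alpha"],
      "properties": {
        "n_subjects": {"type": "integer", "minimum": 1},
        "seed": {"type": "integer"},
        "alpha": {"type": "number", "exclusiveMinimum": 0, "exclusiveMaximum": 1}
      }
    },
    "subjects": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["subject_id", "nlr", "lda", "fsm"],
        "properties": {
          "subject_id": {"type": "string"},
          "nlr": {"type": "object"},
          "lda": {"type": "object"},
          "nlr_selection": {"type": "object"},
          "fsm": {"type": "object"}
        }
      }
    },
    "aggregate": {
      "type": "object",
      "required": ["gesture", "spherical_force", "tip_force"],
      "additionalProperties": {
        "type": "object",
        "properties": {
          "nlr": {"$ref": "#/definitions/aggregateBlock"},
          "lda": {"$ref": "#/definitions/aggregateBlock"}
        }
      }
    },
    "wilcoxon": {
      "type": "object",
      "required": ["gesture", "spherical_force", "tip_force"],
      "additionalProperties": {
        "type": "object",
        "required": ["p_value", "significant", "alpha"],
        "properties": {
          "statistic": {"type": ["number", "null"]},
          "p_value": {"type": "number", "minimum": 0, "maximum": 1},
          "significant": {"type": "boolean"},
          "alpha": {"type": "number"},
          "n_effective": {"type": "integer"}
        }
      }
    },
    "fsm": {
      "type": "object",
      "required": ["gesture_accuracy", "force_accuracy", "force_coverage"]
    }
  },
  "definitions": {
    "aggregateBlock": {
      "type": "object",
      "required": ["per_class", "mean_confusion", "mean_macro_f1"],
      "properties": {
        "mean_macro_f1": {"type": "number", "minimum": 0, "maximum": 100},
        "sd_macro_f1": {"type": "number", "minimum": 0}
      }
    }
  }
}
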