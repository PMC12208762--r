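{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "ankletriage knowledge-base document",
  "type": "object",
  "required": ["version", "groups", "questions", "rules", "recovery_plans", "settings"],
  "properties": {
    "version": {"type": "string"},
    "groups": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["id", "label", "role"],
        "properties": {
          "id": {"type": "string"},
          "label": {"type": "string"},
          "role": {"enum": ["contraindication-screen", "ottawa-findings", "fracture-sign", "sprain-sign", "tens-screen"]}
        }
      }
    },
    "questions": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["id", "group_id", "text", "kind", "positive_when", "applicability"],
        "properties": {
          "id": {"type": "string"},
          "group_id": {"type": "string"},
          "text": {"type": "string"},
          "kind": {"enum": ["boolean", "body-metric"]},
          "positive_when": {"enum": ["affirmative", "negative", "threshold-exceeded"]},
          "applicability": {"enum": ["all", "female-only"]}
        }
      }
    },
    "rules": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["rule_id", "name", "category", "outcome_label", "cases"],
        "properties": {
          "rule_id": {"type": "integer"},
          "name": {"type": "string"},
          "category": {"enum": ["diagnostic", "device-eligibility"]},
          "outcome_label": {"type": "string"},
          "cases": {
            "type": "array",
            "minItems": 1,
            "items": {
              "type": "object",
              "required": ["case_index", "condition"],
              "properties": {
                "case_index": {"type": "integer", "minimum": 1},
                "condition": {"$ref": "#/definitions/condition"}
              }
            }
          }
        }
      }
    },
    "recovery_plans": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["injury_key", "healing_duration_weeks", "residual_symptom_horizon_months", "provisional", "phases"],
        "properties": {
          "injury_key": {"type": "string"},
          "label": {"type": "string"},
          "healing_duration_weeks": {"type": "integer", "minimum": 1},
          "residual_symptom_horizon_months": {"type": "integer", "minimum": 0},
          "provisional": {"type": "boolean"},
          "phases": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["weeks", "instruction"],
              "properties": {"weeks": {"type": "string"}, "instruction": {"type": "string"}}
            }
          }
        }
      }
    },
    "settings": {
      "type": "object",
      "required": ["bmi_elevated_threshold", "rule_priority", "compatibility_flags"],
      "properties": {
        "bmi_elevated_threshold": {"type": "number", "exclusiveMinimum": 0},
        "rule_priority": {"type": "array", "items": {"type": "integer"}},
        "outcome_paths": {"type": "object", "additionalProperties": {"enum": ["visit-clinician", "home-care", "no-action"]}},
        "compatibility_flags": {"type": "object", "additionalProperties": {"type": "boolean"}}
      }
    }
  },
  "definitions": {
    "condition": {
      "oneOf": [
        {
          "type": "object",
          "required": ["op", "group"],
          "properties": {"op": {"enum": ["any", "none"]}, "group": {"type": "string"}}
        },
        {
          "type": "object",
          "required": ["op", "args"],
          "properties": {
            "op": {"enum": ["and", "or"]},
            "args": {"type": "array", "minItems": 1, "items": {"$ref": "#/definitions/condition"}}
          }
        }
      ]
    }
  }
}
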