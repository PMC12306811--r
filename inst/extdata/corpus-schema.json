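{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "litmine linked-corpus document",
  "type": "object",
  "required": ["format", "version", "reviews", "studies", "inclusion_truth"],
  "properties": {
    "format": {"const": "litmine-corpus"},
    "version": {"type": "integer"},
    "reviews": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["review_id", "title", "abstract", "pico", "pub_date"],
        "properties": {
          "review_id": {"type": "string"},
          "title": {"type": "string"},
          "abstract": {"type": "string"},
          "pico": {
            "type": "object",
            "required": ["population", "intervention"],
            "properties": {
              "population": {"type": "string", "minLength": 1},
              "intervention": {"type": "string", "minLength": 1},
              "comparator": {"type": "string"},
              "outcome": {"type": "string"}
            }
          },
          "criteria": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["element", "text", "role"],
              "properties": {
                "element": {"enum": ["P", "I", "C", "O"]},
                "text": {"type": "string", "minLength": 1},
                "role": {"enum": ["inclusion", "exclusion"]}
              }
            }
          },
          "topic_area": {"type": "string"},
          "pub_date": {"type": "string", "format": "date"}
        }
      }
    },
    "studies": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["study_id", "kind", "title", "abstract"],
        "properties": {
          "study_id": {"type": "string"},
          "kind": {"enum": ["publication", "trial_registry"]},
          "title": {"type": "string"},
          "abstract": {"type": "string"},
          "full_text": {"type": ["string", "null"]},
          "table_text": {"type": ["array", "null"], "items": {"type": "string"}},
          "pub_date": {"type": ["string", "null"], "format": "date"},
          "nct_link": {"type": ["string", "null"], "pattern": "^NCT[0-9]{8}$"},
          "registry_truth": {
            "type": ["object", "null"],
            "properties": {
              "conditions": {"type": "array", "items": {"type": "string"}},
              "interventions": {"type": "array", "items": {"type": "string"}},
              "enrollment": {"type": "integer", "minimum": 0},
              "study_type": {"type": "string"},
              "arms": {
                "type": "array",
                "items": {
                  "type": "object",
                  "required": ["label"],
                  "properties": {
                    "label": {"type": "string", "minLength": 1},
                    "arm_type": {"type": "string"},
                    "description": {"type": "string"},
                    "intervention_names": {"type": "array", "items": {"type": "string"}}
                  }
                }
              },
              "participant_measures": {"type": "array"},
              "outcome_results": {"type": "array"}
            }
          },
          "planted_terms": {
            "type": ["object", "null"],
            "properties": {
              "population": {"type": "array", "items": {"type": "string"}},
              "intervention": {"type": "array", "items": {"type": "string"}}
            }
          }
        }
      }
    },
    "inclusion_truth": {
      "type": "object",
      "additionalProperties": {"type": "array", "items": {"type": "string"}}
    }
  }
}
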