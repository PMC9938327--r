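{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "PCRT questionnaire cohort",
  "type": "object",
  "required": ["respondents"],
  "properties": {
    "respondents": {
      "type": "array",
      "items": { "$ref": "#/definitions/patient_response" }
    }
  },
  "definitions": {
    "tristate": { "enum": ["yes", "no", "unknown"] },
    "cancer_event": {
      "type": "object",
      "required": ["cancer_type", "dx_at_or_before_50"],
      "properties": {
        "cancer_type": {
          "enum": ["pancreatic", "breast", "ovarian", "colorectal",
                   "prostate", "thyroid", "melanoma", "other"]
        },
        "dx_at_or_before_50": { "$ref": "#/definitions/tristate" },
        "label": { "type": ["string", "null"] }
      }
    },
    "person_history": {
      "type": "object",
      "required": ["relation", "events"],
      "properties": {
        "relation": { "enum": ["self", "mother", "father", "sibling"] },
        "relation_index": { "type": "integer", "minimum": 1 },
        "events": {
          "type": "array",
          "items": { "$ref": "#/definitions/cancer_event" }
        }
      }
    },
    "nod_responses": {
      "type": "object",
      "required": ["section_completed"],
      "properties": {
        "section_completed": { "type": "boolean" },
        "weight_current_lb": { "type": ["number", "null"], "exclusiveMinimum": 0 },
        "weight_one_year_ago_lb": { "type": ["number", "null"], "exclusiveMinimum": 0 },
        "glucose_elevated": { "$ref": "#/definitions/tristate" },
        "diabetes_or_glucose_intolerance": { "type": "boolean" },
        "glycemic_change_around_age_50_or_later": { "$ref": "#/definitions/tristate" }
      }
    },
    "patient_response": {
      "type": "object",
      "required": ["patient_id", "age", "sex", "persons", "nod"],
      "properties": {
        "patient_id": { "type": "string" },
        "age": { "type": "integer", "minimum": 18 },
        "sex": { "enum": ["female", "male"] },
        "ethnicity": { "enum": ["White", "African American", "Asian", "Other"] },
        "ashkenazi_mother": { "$ref": "#/definitions/tristate" },
        "ashkenazi_father": { "$ref": "#/definitions/tristate" },
        "current_smoker": { "type": "boolean" },
        "prior_genetic_testing": { "type": "boolean" },
        "preexisting_pancreatic_cancer": { "type": "boolean" },
        "persons": {
          "type": "array",
          "items": { "$ref": "#/definitions/person_history" }
        },
        "nod": { "$ref": "#/definitions/nod_responses" }
      }
    }
  }
}
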