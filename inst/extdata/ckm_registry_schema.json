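{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "ckm_registry_schema.json",
  "title": "CKM ICD-10-CM code-set registry",
  "description": "Authoritative JSON layout for CKM stage 0-4 code sets. load_registry() enforces these constraints natively and reports violations by JSON path.",
  "type": "object",
  "required": ["version", "code_sets", "stages"],
  "properties": {
    "version": {"type": "string"},
    "code_sets": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["name", "role", "acuity", "patterns"],
        "properties": {
          "name": {"type": "string", "minLength": 1},
          "role": {"enum": ["stage_core", "supplementary", "exclusion",
                            "substage_marker"]},
          "acuity": {"enum": ["chronic", "acute"]},
          "patterns": {
            "type": "array",
            "minItems": 1,
            "items": {"$ref": "#/definitions/pattern"}
          }
        }
      }
    },
    "stages": {
      "type": "array",
      "minItems": 5,
      "maxItems": 5,
      "items": {
        "type": "object",
        "required": ["stage", "core_sets", "supplementary_sets",
                     "exclusion_sets", "cooccurrence_rule"],
        "properties": {
          "stage": {"type": "integer", "minimum": 0, "maximum": 4},
          "core_sets": {"type": "array", "items": {"type": "string"}},
          "supplementary_sets": {"type": "array",
                                 "items": {"type": "string"}},
          "exclusion_sets": {"type": "array",
                             "items": {"type": "string"}},
          "cooccurrence_rule": {"type": "string"}
        }
      }
    }
  },
  "definitions": {
    "pattern": {
      "type": "object",
      "required": ["kind", "value"],
      "properties": {
        "kind": {"enum": ["literal", "family", "range"]},
        "value": {
          "type": "string",
          "pattern": "^[A-Z][A-Z0-9]{2,6}(-[A-Z][A-Z0-9]{2,6})?$"
        },
        "exclusions": {
          "type": "array",
          "items": {"$ref": "#/definitions/pattern"}
        }
      }
    }
  }
}
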