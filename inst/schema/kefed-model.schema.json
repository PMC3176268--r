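{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "kefed-model.schema.json",
  "title": "Experimental-design (KEfED) model document",
  "type": "object",
  "required": ["id", "name", "description", "nodes", "edges"],
  "properties": {
    "id": {"type": "string", "minLength": 1},
    "name": {"type": "string"},
    "description": {"type": "string"},
    "nodes": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "kind"],
        "properties": {
          "id": {"type": "string", "minLength": 1},
          "kind": {
            "enum": ["activity", "material", "parameter", "constant",
                     "measurement", "branch", "fork"]
          },
          "label": {"type": "string"},
          "ontology_term": {
            "type": "string",
            "pattern": "^[A-Za-z_][A-Za-z0-9_.-]*:\\S+$"
          },
          "domain": {
            "type": "object",
            "required": ["kind"],
            "properties": {
              "kind": {
                "enum": ["nominal", "ordinal", "free_text",
                         "region_extent", "numeric"]
              },
              "levels": {
                "type": "array",
                "items": {"type": "string"},
                "uniqueItems": true
              },
              "units": {"type": "string"}
            }
          }
        }
      }
    },
    "edges": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["source", "target", "kind"],
        "properties": {
          "source": {"type": "string"},
          "target": {"type": "string"},
          "kind": {"enum": ["flow", "parameter_of", "measurement_of"]}
        }
      }
    }
  }
}
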