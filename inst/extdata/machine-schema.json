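{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "stabledose machine library",
  "type": "object",
  "required": ["beams"],
  "properties": {
    "medium": {"type": "string"},
    "range_model": {
      "type": "object",
      "required": ["mode"],
      "properties": {
        "mode": {"enum": ["power_law", "table"]},
        "a": {"type": "number", "exclusiveMinimum": 0},
        "p": {"type": "number", "exclusiveMinimum": 0},
        "table": {
          "type": "array",
          "minItems": 2,
          "items": {
            "type": "object",
            "required": ["energy_MeV", "range_mm"],
            "properties": {
              "energy_MeV": {"type": "number", "exclusiveMinimum": 0},
              "range_mm": {"type": "number", "exclusiveMinimum": 0}
            }
          }
        }
      }
    },
    "beams": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["energy_MeV", "range_mm", "depths"],
        "properties": {
          "energy_MeV": {"type": "number", "exclusiveMinimum": 0},
          "range_mm": {"type": "number", "exclusiveMinimum": 0},
          "depths": {
            "type": "array",
            "minItems": 3,
            "items": {
              "type": "object",
              "required": ["z_mm", "alpha", "gamma_mm", "integral_dose"],
              "properties": {
                "z_mm": {"type": "number", "minimum": 0},
                "alpha": {
                  "type": "number", "exclusiveMinimum": 1, "maximum": 2,
                  "description": "alpha <= 1 rejected: 2D shell normalization diverges"
                },
                "gamma_mm": {"type": "number", "exclusiveMinimum": 0},
                "integral_dose": {"type": "number", "minimum": 0}
              }
            }
          }
        }
      }
    }
  }
}
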