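{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "svgheatmap data object",
  "type": "object",
  "required": ["rows", "cols", "values"],
  "properties": {
    "rows": {
      "type": "array",
      "items": { "type": "string" },
      "minItems": 1
    },
    "cols": {
      "type": "array",
      "items": { "type": "string" },
      "minItems": 1
    },
    "values": {
      "description": "Row-major grid, one inner array per matrix row; null marks a missing cell.",
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "array",
        "minItems": 1,
        "items": { "type": ["number", "null"] }
      }
    },
    "flags": {
      "description": "Optional per-cell flags, same shape as values.",
      "type": "array",
      "items": {
        "type": "array",
        "items": { "enum": ["NONE", "WILDTYPE", "MISSING"] }
      }
    }
  }
}
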