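{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "svgheatmap configuration object",
  "type": "object",
  "required": ["scheme"],
  "properties": {
    "target": {
      "description": "Target element identifier; stored verbatim, unused in file output.",
      "type": "string"
    },
    "scheme": {
      "description": "Built-in color scheme name, e.g. blue-white-red or green-black-red.",
      "type": "string"
    },
    "range": {
      "type": "object",
      "required": ["min", "max"],
      "properties": {
        "min": { "type": "number" },
        "max": { "type": "number" },
        "mid": { "type": "number" }
      }
    },
    "canvas": {
      "type": "object",
      "required": ["width", "height"],
      "properties": {
        "width": { "type": "number", "exclusiveMinimum": 0 },
        "height": { "type": "number", "exclusiveMinimum": 0 }
      }
    },
    "minCellSize": { "type": "number", "exclusiveMinimum": 0 },
    "zoomStartCol": { "type": "number", "minimum": 0 },
    "tooltips": { "type": "boolean" }
  }
}
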