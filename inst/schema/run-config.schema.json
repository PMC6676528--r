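{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "wgdfrac run configuration",
  "type": "object",
  "required": ["M1"],
  "properties": {
    "type": { "enum": ["schedule", "scenario"] },
    "M1": { "type": "integer", "minimum": 1 },
    "events": {
      "type": "array",
      "items": { "$ref": "#/$defs/event" },
      "description": "schedule only: WGD events oldest-first, one observation last"
    },
    "shared": {
      "type": "array",
      "items": { "$ref": "#/$defs/event" },
      "description": "scenario only: shared WGDs oldest-first, one speciation last"
    },
    "branch_a": { "type": "array", "items": { "$ref": "#/$defs/event" } },
    "branch_b": { "type": "array", "items": { "$ref": "#/$defs/event" } },
    "decay": {
      "type": "object",
      "properties": {
        "C": { "type": "number", "exclusiveMinimum": 0 },
        "lambda": { "type": "number", "exclusiveMinimum": 0 }
      }
    },
    "sd_model": {
      "type": "object",
      "properties": {
        "intercept": { "type": "number" },
        "slope": { "type": "number" }
      }
    },
    "replicates": { "type": "integer", "minimum": 1 }
  },
  "$defs": {
    "event": {
      "type": "object",
      "required": ["kind", "time"],
      "properties": {
        "kind": { "enum": ["wgd", "speciation", "observation"] },
        "time": { "type": "number", "minimum": 0, "description": "My before present" },
        "ploidy": { "type": "integer", "minimum": 2 },
        "u": {
          "type": "array",
          "items": { "type": "number", "minimum": 0, "maximum": 1 },
          "description": "survival probabilities u_0..u_r, summing to 1"
        }
      }
    }
  }
}
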