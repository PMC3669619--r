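{
  "$id": "phylotastic/datelife-response",
  "title": "MRCA age estimate response",
  "type": "object",
  "required": ["query", "per_source", "overall_range"],
  "properties": {
    "query": {"type": "array", "minItems": 2, "items": {"type": "string"}},
    "per_source": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["id", "citation", "mrca_age", "n_matched", "sample_ages"],
        "properties": {
          "id": {"type": "string"},
          "citation": {"type": "string"},
          "mrca_age": {"type": "number"},
          "n_matched": {"type": "integer"},
          "sample_ages": {"type": "array", "minItems": 1, "items": {"type": "number"}}
        }
      }
    },
    "overall_range": {"type": "array", "minItems": 2, "items": {"type": "number"}}
  }
}
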