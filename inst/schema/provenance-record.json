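{
  "$id": "phylotastic/provenance-record",
  "title": "Pipeline provenance record",
  "type": "object",
  "required": ["tool", "version", "timestamp", "source_tree", "operations",
               "names", "ledger"],
  "properties": {
    "tool": {"type": "string"},
    "version": {"type": "string"},
    "timestamp": {"type": "string"},
    "source_tree": {
      "type": "object",
      "required": ["id", "citation"],
      "properties": {
        "id": {"type": "string"},
        "citation": {"type": "string"}
      }
    },
    "operations": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["op"],
        "properties": {"op": {"type": "string"}}
      }
    },
    "names": {
      "type": "object",
      "required": ["submitted", "resolved", "unresolved", "not_in_source_tree"],
      "properties": {
        "submitted": {"type": "array", "items": {"type": "string"}},
        "resolved": {
          "type": "array",
          "items": {
            "type": "object",
            "required": ["submitted", "matched", "score"],
            "properties": {
              "submitted": {"type": "string"},
              "matched": {"type": "string"},
              "score": {"type": "number"},
              "source": {"type": "string"},
              "ambiguous": {"type": "boolean"}
            }
          }
        },
        "unresolved": {"type": "array", "items": {"type": "string"}},
        "not_in_source_tree": {"type": "array", "items": {"type": "string"}}
      }
    },
    "ledger": {
      "type": "object",
      "required": ["submitted", "kept", "unresolved", "in_tree",
                   "not_in_source_tree"],
      "properties": {
        "submitted": {"type": "integer"},
        "kept": {"type": "integer"},
        "unresolved": {"type": "integer"},
        "in_tree": {"type": "integer"},
        "not_in_source_tree": {"type": "integer"}
      }
    }
  }
}
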