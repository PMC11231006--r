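{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "Question-answer pair (one JSONL record)",
  "type": "object",
  "required": ["question", "answer", "template_id", "frame_id", "qtype", "complexity"],
  "properties": {
    "question": {"type": "string"},
    "answer": {"type": "string"},
    "template_id": {"type": "string"},
    "binding": {
      "type": "object",
      "additionalProperties": {"type": ["string", "null"]}
    },
    "program": {
      "type": ["array", "null"],
      "items": {
        "type": "object",
        "required": ["op"],
        "properties": {
          "op": {
            "enum": ["scene", "filter_name", "filter_color", "filter_location",
                     "filter_type", "relate_spatial", "relate_action", "unique",
                     "query_name", "query_color", "query_location", "query_type",
                     "query_verb", "exist", "count", "intersect"]
          },
          "arg": {"type": ["string", "null"]},
          "inputs": {"type": "array", "items": {"type": "integer", "minimum": 1}}
        }
      }
    },
    "frame_id": {"type": "string"},
    "qtype": {
      "enum": ["query_object", "query_attribute", "query_relation",
               "existence", "counting"]
    },
    "complexity": {"enum": ["zero_hop", "one_hop", "single_and"]}
  }
}
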