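{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "Surgical scene graph (one frame)",
  "type": "object",
  "required": ["frame_id", "frame_dims", "objects", "spatial_edges", "action_edges"],
  "properties": {
    "frame_id": {"type": "string"},
    "frame_dims": {
      "type": "object",
      "required": ["width", "height"],
      "properties": {
        "width": {"type": "number", "exclusiveMinimum": 0},
        "height": {"type": "number", "exclusiveMinimum": 0}
      }
    },
    "objects": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["object_id", "name", "category", "color", "bbox", "location"],
        "properties": {
          "object_id": {"type": "string"},
          "name": {"type": "string"},
          "category": {"enum": ["instrument", "anatomy"]},
          "color": {"type": "string"},
          "bbox": {
            "type": "object",
            "required": ["x1", "y1", "x2", "y2"],
            "properties": {
              "x1": {"type": "number", "minimum": 0},
              "y1": {"type": "number", "minimum": 0},
              "x2": {"type": "number", "exclusiveMinimum": 0},
              "y2": {"type": "number", "exclusiveMinimum": 0}
            }
          },
          "location": {
            "enum": ["top-left", "top-mid", "top-right",
                     "mid-left", "mid-mid", "mid-right",
                     "bottom-left", "bottom-mid", "bottom-right"]
          }
        }
      }
    },
    "spatial_edges": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["source", "relation", "target"],
        "properties": {
          "source": {"type": "string"},
          "relation": {"enum": ["left of", "right of", "above", "below"]},
          "target": {"type": "string"}
        }
      }
    },
    "action_edges": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["instrument_id", "verb", "target_id"],
        "properties": {
          "instrument_id": {"type": "string"},
          "verb": {"type": "string"},
          "target_id": {"type": "string"}
        }
      }
    }
  }
}
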