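{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "telebaci analysis report",
  "type": "object",
  "required": ["package", "seed", "alpha", "n_test", "n_control",
               "matching", "outcomes", "baseline", "mortality"],
  "properties": {
    "package": {"type": "string"},
    "seed": {"type": "integer"},
    "alpha": {"type": "number"},
    "n_test": {"type": "integer"},
    "n_control": {"type": "integer"},
    "matching": {
      "type": "object",
      "required": ["n_pairs", "n_unmatched", "mean_distance"]
    },
    "outcomes": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "required": ["test", "control", "difference"],
        "properties": {
          "test": {"type": "object", "required": ["comparison"]},
          "control": {"type": "object", "required": ["comparison"]},
          "difference": {"type": "object", "required": ["comparison"]}
        }
      }
    },
    "baseline": {
      "type": "object",
      "required": ["pre_start", "pre_end"]
    },
    "mortality": {
      "type": "object",
      "required": ["observed", "expected_total", "reduction_pct"]
    }
  }
}
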