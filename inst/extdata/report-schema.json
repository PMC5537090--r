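{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "autobaa structured bone-age report",
  "type": "object",
  "required": ["source_id", "sex", "predicted_bone_age", "topk_suggestions",
               "maturity_stage", "pipeline_versions", "timestamp"],
  "properties": {
    "source_id": {"type": "string"},
    "sex": {"enum": ["female", "male"]},
    "predicted_bone_age": {"type": "integer", "minimum": 5, "maximum": 18},
    "topk_suggestions": {
      "type": "array", "minItems": 3, "maxItems": 5,
      "items": {
        "type": "object",
        "required": ["bone_age", "probability"],
        "properties": {
          "bone_age": {"type": "integer", "minimum": 5, "maximum": 18},
          "probability": {"type": "number", "minimum": 0, "maximum": 1}
        }
      }
    },
    "maturity_stage": {"enum": ["prepuberty", "early_mid_puberty",
                                "late_puberty", "postpuberty"]},
    "probabilities": {"type": "object"},
    "pipeline_versions": {"type": "object"},
    "timestamp": {"type": "string"}
  }
}
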