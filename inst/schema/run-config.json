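{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "hitloop run configuration",
  "description": "Configuration consumed by cmd_select / cmd_run / cmd_validate. The 'required' map lists mandatory keys per subcommand; validate_run_config() enforces it.",
  "required": {
    "run": ["corpus", "codebook", "out"],
    "select": ["corpus", "codebook", "out"],
    "validate": ["corpus", "codebook", "session_dir"]
  },
  "properties": {
    "corpus": {"type": "string", "description": "path to the records CSV"},
    "codebook": {
      "type": "object",
      "properties": {
        "task_name": {"type": "string"},
        "categories": {"type": "array", "items": {"type": "string"}, "minItems": 2}
      }
    },
    "schema": {
      "type": "object",
      "properties": {
        "id": {"type": "string"}, "text": {"type": "string"},
        "gold": {"type": "string"},
        "cat_features": {"type": "array", "items": {"type": "string"}},
        "num_features": {"type": "array", "items": {"type": "string"}}
      }
    },
    "featurizer": {"type": "object", "description": "arguments of featurizer_config()"},
    "family": {
      "type": "object",
      "properties": {
        "name": {"enum": ["tree-ensemble", "maxent-linear"]},
        "hyperparameters": {"type": "object"}
      }
    },
    "families": {"type": "array", "description": "families for selection runs"},
    "grid": {"type": "object", "description": "featurizer variant grid for selection"},
    "loop": {"type": "object", "description": "arguments of loop_config()"},
    "oracle": {"type": "object", "description": "arguments of oracle_config()"},
    "n_seed_labels": {"type": "integer"},
    "ablation_tolerance": {"type": "number"},
    "per_class_n": {"type": "integer"},
    "session_dir": {"type": "string"},
    "seed": {"type": "integer"},
    "out": {"type": "string", "description": "output directory (or file for synth)"}
  }
}
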