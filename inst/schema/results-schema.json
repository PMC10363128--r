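{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "asrtlab analysis results bundle",
  "type": "object",
  "required": ["seed", "n_blocks", "blocks_per_epoch", "iqd_k",
               "n_participants", "analyses"],
  "properties": {
    "seed": {"type": "integer"},
    "n_blocks": {"type": "integer", "minimum": 1},
    "blocks_per_epoch": {"type": "integer", "minimum": 1},
    "iqd_k": {"type": "number", "minimum": 0},
    "n_participants": {
      "type": "object",
      "required": ["NTP", "ASD"],
      "properties": {
        "NTP": {"type": "integer", "minimum": 2},
        "ASD": {"type": "integer", "minimum": 2}
      }
    },
    "analyses": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "required": ["dv", "anova", "gg_epsilon", "epochwise"],
        "properties": {
          "dv": {"enum": ["median_rt_ms", "mean_accuracy"]},
          "anova": {
            "type": "array",
            "items": {"$ref": "#/definitions/effect"}
          },
          "gg_epsilon": {"type": "object"},
          "epochwise": {
            "type": "array",
            "items": {"$ref": "#/definitions/epoch_test"}
          }
        }
      }
    }
  },
  "definitions": {
    "effect": {
      "type": "object",
      "required": ["effect", "F", "df_num", "df_den", "p", "partial_eta_sq"],
      "properties": {
        "effect": {"type": "string"},
        "F": {"type": "number"},
        "df_num": {"type": "integer"},
        "df_den": {"type": "integer"},
        "p": {"type": "number", "minimum": 0, "maximum": 1},
        "partial_eta_sq": {"type": "number", "minimum": 0, "maximum": 1},
        "bf_excl": {"type": "number", "exclusiveMinimum": 0}
      }
    },
    "epoch_test": {
      "type": "object",
      "required": ["epoch", "mean_score", "t", "df", "p", "p_holm"],
      "properties": {
        "epoch": {"type": "integer", "minimum": 1},
        "mean_score": {"type": "number"},
        "t": {"type": "number"},
        "df": {"type": "integer", "minimum": 1},
        "p": {"type": "number", "minimum": 0, "maximum": 1},
        "p_holm": {"type": "number", "minimum": 0, "maximum": 1}
      }
    }
  }
}
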