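{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "pathrepo repository document",
  "description": "Four-layer pathway repository: vocabularies, entities, localized entities, typed interactions with role-tagged participants, and pathways as unordered interaction collections. Cross-references are by id; hierarchy parents are ids with null for roots.",
  "type": "object",
  "required": ["format_version", "organisms", "entity_types",
               "interaction_types", "cell_locations", "pathway_classes",
               "entities", "local_entities", "interactions", "pathways"],
  "properties": {
    "format_version": {"const": "1.0"},
    "organisms": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "name"],
        "properties": {
          "id": {"type": "string", "minLength": 1},
          "name": {"type": "string", "minLength": 1}
        }
      }
    },
    "entity_types": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["id", "label"],
        "properties": {
          "id": {"type": "string", "minLength": 1},
          "label": {"type": "string", "minLength": 1}
        }
      }
    },
    "interaction_types": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "label", "is_regulatory"],
        "properties": {
          "id": {"type": "string", "minLength": 1},
          "label": {"type": "string", "minLength": 1},
          "is_regulatory": {"type": "boolean"}
        }
      }
    },
    "cell_locations": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "name"],
        "properties": {
          "id": {"type": "string", "minLength": 1},
          "name": {"type": "string", "minLength": 1},
          "parent": {"type": ["string", "null"]}
        }
      }
    },
    "pathway_classes": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "name"],
        "properties": {
          "id": {"type": "string", "minLength": 1},
          "name": {"type": "string", "minLength": 1},
          "parent": {"type": ["string", "null"]}
        }
      }
    },
    "entities": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "name", "entity_type"],
        "properties": {
          "id": {"type": "string", "minLength": 1},
          "name": {"type": "string", "minLength": 1},
          "entity_type": {"type": "string"},
          "organism": {"type": ["string", "null"]},
          "synonyms": {"type": "array", "items": {"type": "string"}}
        }
      }
    },
    "local_entities": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "entity", "location"],
        "properties": {
          "id": {"type": "string", "minLength": 1},
          "entity": {"type": "string"},
          "location": {"type": "string"}
        }
      }
    },
    "interactions": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "interaction_type", "participants"],
        "properties": {
          "id": {"type": "string", "minLength": 1},
          "interaction_type": {"type": "string"},
          "organism": {"type": ["string", "null"]},
          "participants": {
            "type": "array",
            "minItems": 1,
            "items": {
              "type": "object",
              "required": ["local_entity", "role"],
              "properties": {
                "local_entity": {"type": "string"},
                "role": {"enum": ["input", "output", "modifier"]},
                "modifier_effect": {
                  "enum": ["catalysis", "activation", "inhibition"]
                },
                "stoichiometry": {"type": "number", "exclusiveMinimum": 0}
              }
            }
          }
        }
      }
    },
    "pathways": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "name", "organism", "interactions"],
        "properties": {
          "id": {"type": "string", "minLength": 1},
          "name": {"type": "string", "minLength": 1},
          "organism": {"type": "string"},
          "pathway_class": {"type": ["string", "null"]},
          "interactions": {"type": "array", "items": {"type": "string"}}
        }
      }
    }
  }
}
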