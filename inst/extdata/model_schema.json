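{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "$id": "txasim-model/1",
  "title": "txasim reaction-network model file",
  "type": "object",
  "required": ["species", "reactions"],
  "properties": {
    "schema": {"const": "txasim-model/1"},
    "name": {"type": "string"},
    "version": {"type": "string"},
    "provenance": {"type": "string"},
    "species": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["name", "initial_concentration"],
        "properties": {
          "name": {"type": "string", "minLength": 1},
          "initial_concentration": {"type": "number", "minimum": 0,
            "description": "expressed in `unit`; internal state is molar"},
          "unit": {"enum": ["M", "mM", "uM", "nM", "pM"]},
          "tags": {"type": "array", "items": {"type": "string"}}
        }
      }
    },
    "reactions": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "law"],
        "properties": {
          "id": {"type": "string", "minLength": 1},
          "reactants": {"$ref": "#/$defs/side"},
          "products": {"$ref": "#/$defs/side"},
          "enzyme": {"type": "string",
            "description": "michaelis_menten kinds only; not consumed"},
          "activator": {"type": "string",
            "description": "michaelis_menten_activated only; saturating cofactor"},
          "law": {
            "type": "object",
            "required": ["kind", "params"],
            "properties": {
              "kind": {"enum": ["mass_action_irreversible",
                                "mass_action_reversible",
                                "michaelis_menten",
                                "michaelis_menten_activated"]},
              "params": {
                "type": "object",
                "description": "exact parameter set per kind: k | kon,koff | kcat,Km | kcat,Km,act_factor,act_Km; units M and s",
                "additionalProperties": {"type": "number", "exclusiveMinimum": 0}
              }
            }
          },
          "note": {"type": "string", "description": "free-text provenance"}
        }
      }
    }
  },
  "$defs": {
    "side": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["species"],
        "properties": {
          "species": {"type": "string"},
          "stoich": {"type": "integer", "minimum": 1}
        }
      }
    }
  }
}
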