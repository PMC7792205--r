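{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "https://example.org/sroikit/scenario.schema.json",
  "title": "SROI scenario",
  "description": "A Social Return on Investment scenario: one annual beneficiary cohort, a set of valued outcomes, impact adjustments, an annual investment and a discount rate. Fractions may be given as decimals (0.26) or percent strings (\"26%\"). The same schema is accepted as YAML, and as a CSV bundle (scenario.csv field/value pairs with adjustment fields flattened as adjustments.<name>, plus outcomes.csv).",
  "type": "object",
  "required": ["population", "investment", "outcomes"],
  "definitions": {
    "fraction": {
      "description": "A fraction of one, written as a decimal in [0,1] or as a percent string such as \"26%\" or \"0.008%\" (divided by 100 on parse).",
      "oneOf": [
        {"type": "number", "minimum": 0, "maximum": 1},
        {"type": "string", "pattern": "^\\s*[0-9.eE+-]+\\s*%?\\s*$"}
      ]
    },
    "outcome": {
      "type": "object",
      "required": ["name", "beneficiary", "incidence", "risk_reduction",
                   "unit_value", "duration_years"],
      "properties": {
        "name": {"type": "string"},
        "beneficiary": {"type": "string", "enum": ["infant", "mother"]},
        "incidence": {"$ref": "#/definitions/fraction"},
        "risk_reduction": {"$ref": "#/definitions/fraction"},
        "unit_value": {"type": "number", "minimum": 0,
                       "description": "AUD per affected case (or per person-year for earnings proxies)"},
        "duration_years": {"type": "integer", "minimum": 1},
        "printed_value": {"type": "number",
                          "description": "Optional externally reported annual value carried for reproduction of a published analysis; never replaces the computed value."}
      },
      "additionalProperties": false
    }
  },
  "properties": {
    "population": {"type": "number", "minimum": 1,
                   "description": "Beneficiary units (e.g. mother-infant dyads) per year"},
    "breastfeeding_rate": {"$ref": "#/definitions/fraction",
                           "description": "Descriptive cohort metadata; multiplied into valuations only when apply_breastfeeding_rate is true"},
    "apply_breastfeeding_rate": {"type": "boolean", "default": false},
    "investment": {"type": "number", "exclusiveMinimum": 0,
                   "description": "AUD per year"},
    "discount_rate": {
      "oneOf": [
        {"type": "number", "minimum": 0},
        {"type": "string", "pattern": "^\\s*[0-9.eE+-]+\\s*%?\\s*$"}
      ],
      "default": 0.04
    },
    "total_benefit_override": {"type": "number",
                               "description": "Optional AUD total replacing the computed outcome sum as the ratio basis (simple mode)"},
    "adjustments": {
      "type": "object",
      "properties": {
        "deadweight": {"$ref": "#/definitions/fraction"},
        "displacement": {"$ref": "#/definitions/fraction"},
        "attribution": {"$ref": "#/definitions/fraction"},
        "drop_off": {"$ref": "#/definitions/fraction"}
      },
      "additionalProperties": false
    },
    "outcomes": {
      "type": "array",
      "minItems": 1,
      "items": {"$ref": "#/definitions/outcome"}
    }
  },
  "additionalProperties": false
}
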