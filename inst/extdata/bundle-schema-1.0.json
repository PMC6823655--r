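{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "$id": "bpscore/bundle-schema-1.0.json",
  "title": "Multi-source client record bundle",
  "description": "One array per source table; every record carries an opaque client_id. Dates are ISO-8601 strings.",
  "type": "object",
  "properties": {
    "schema_version": { "const": "1.0" },
    "encounters": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["client_id", "date", "booked", "attended"],
        "properties": {
          "client_id": { "type": "string", "minLength": 1 },
          "source_system": { "type": ["string", "null"] },
          "date": { "type": "string", "format": "date" },
          "program": { "type": ["string", "null"] },
          "booked": { "type": "boolean" },
          "attended": { "type": "boolean" }
        }
      }
    },
    "honos": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["client_id", "date", "item1", "item2", "item3", "item4", "item5", "item6", "item7", "item8", "item9", "item10", "item11", "item12"],
        "properties": {
          "client_id": { "type": "string", "minLength": 1 },
          "date": { "type": "string", "format": "date" },
          "item1": { "type": "integer", "minimum": 0, "maximum": 4 },
          "item2": { "type": "integer", "minimum": 0, "maximum": 4 },
          "item3": { "type": "integer", "minimum": 0, "maximum": 4 },
          "item4": { "type": "integer", "minimum": 0, "maximum": 4 },
          "item5": { "type": "integer", "minimum": 0, "maximum": 4 },
          "item6": { "type": "integer", "minimum": 0, "maximum": 4 },
          "item7": { "type": "integer", "minimum": 0, "maximum": 4 },
          "item8": { "type": "integer", "minimum": 0, "maximum": 4 },
          "item9": { "type": "integer", "minimum": 0, "maximum": 4 },
          "item10": { "type": "integer", "minimum": 0, "maximum": 4 },
          "item11": { "type": "integer", "minimum": 0, "maximum": 4 },
          "item12": { "type": "integer", "minimum": 0, "maximum": 4 }
        }
      }
    },
    "problems": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["client_id", "code"],
        "properties": {
          "client_id": { "type": "string", "minLength": 1 },
          "code": { "type": "string", "minLength": 1 },
          "label": { "type": ["string", "null"] },
          "is_sumh": { "type": ["boolean", "null"] },
          "is_complex_care": { "type": ["boolean", "null"] },
          "is_neurodegenerative": { "type": ["boolean", "null"] }
        }
      }
    },
    "vitals": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["client_id", "date"],
        "properties": {
          "client_id": { "type": "string", "minLength": 1 },
          "date": { "type": "string", "format": "date" },
          "systolic_bp": { "type": ["number", "null"], "exclusiveMinimum": 0 },
          "diastolic_bp": { "type": ["number", "null"], "exclusiveMinimum": 0 },
          "bmi": { "type": ["number", "null"], "exclusiveMinimum": 0 }
        }
      }
    },
    "ed_visits": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["client_id", "date", "ctas_level"],
        "properties": {
          "client_id": { "type": "string", "minLength": 1 },
          "date": { "type": "string", "format": "date" },
          "ctas_level": { "type": "integer", "minimum": 1, "maximum": 5 }
        }
      }
    },
    "admissions": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["client_id", "admit_date"],
        "properties": {
          "client_id": { "type": "string", "minLength": 1 },
          "admit_date": { "type": "string", "format": "date" },
          "discharge_date": { "type": ["string", "null"], "format": "date" }
        }
      }
    },
    "flags": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["client_id", "flag_kind"],
        "properties": {
          "client_id": { "type": "string", "minLength": 1 },
          "flag_kind": {
            "enum": ["PWD_FORM", "SHX_CODE", "INTERRAI_MDS", "MOBILITY_ASSESSMENT", "VIOLENCE_ALERT", "EXTENDED_LEAVE"]
          },
          "date": { "type": ["string", "null"], "format": "date" }
        }
      }
    },
    "phq9": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["client_id", "date", "total"],
        "properties": {
          "client_id": { "type": "string", "minLength": 1 },
          "date": { "type": "string", "format": "date" },
          "total": { "type": "integer", "minimum": 0, "maximum": 27 }
        }
      }
    }
  }
}
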