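{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "$id": "https://example.org/emaflow/protocol.schema.json",
  "title": "emaflow study protocol",
  "type": "object",
  "required": ["study_id", "study_name", "conditions", "modules"],
  "additionalProperties": false,
  "properties": {
    "study_id": { "type": "string" },
    "study_name": { "type": "string" },
    "instructions": { "type": "string" },
    "banner_url": { "type": "string" },
    "support_email": { "type": "string" },
    "support_url": { "type": "string" },
    "ethics_statement": { "type": "string" },
    "post_url": { "type": "string" },
    "cache_media": { "type": "boolean" },
    "conditions": {
      "type": "array", "minItems": 1,
      "items": { "type": "string" }, "uniqueItems": true
    },
    "modules": { "type": "array", "items": { "$ref": "#/$defs/module" } }
  },
  "$defs": {
    "module": {
      "type": "object",
      "required": ["id", "type", "name", "sections"],
      "additionalProperties": false,
      "properties": {
        "id": { "type": "string" },
        "type": { "enum": ["survey", "info", "video", "audio"] },
        "name": { "type": "string" },
        "condition": { "type": "string", "default": "*" },
        "schedule": { "$ref": "#/$defs/schedule" },
        "graph": { "$ref": "#/$defs/graph" },
        "shuffle_sections": { "type": "boolean", "default": false },
        "sections": {
          "type": "array", "minItems": 1,
          "items": { "$ref": "#/$defs/section" }
        }
      }
    },
    "schedule": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "times": {
          "type": "array",
          "items": { "type": "string", "pattern": "^([01][0-9]|2[0-3]):[0-5][0-9]$" }
        },
        "start_offset_days": { "type": "integer", "default": 0 },
        "duration_days": { "type": "integer", "minimum": 0, "default": 1 },
        "random": { "type": "boolean", "default": false },
        "random_offset_minutes": { "type": "integer", "minimum": 0, "default": 0 },
        "sticky": { "type": "boolean", "default": false },
        "timeout": { "type": "boolean", "default": false },
        "timeout_minutes": { "type": "integer", "minimum": 0, "default": 0 },
        "alert_title": { "type": "string" },
        "alert_message": { "type": "string" }
      },
      "allOf": [
        {
          "if": { "properties": { "random": { "const": true } } },
          "then": { "properties": { "random_offset_minutes": { "exclusiveMinimum": 0 } } }
        },
        {
          "if": { "properties": { "timeout": { "const": true } } },
          "then": { "properties": { "timeout_minutes": { "exclusiveMinimum": 0 } } }
        }
      ]
    },
    "section": {
      "type": "object",
      "required": ["elements"],
      "additionalProperties": false,
      "properties": {
        "name": { "type": "string" },
        "shuffle": { "type": "boolean", "default": false },
        "elements": {
          "type": "array", "minItems": 1,
          "items": { "$ref": "#/$defs/element" }
        }
      }
    },
    "element": {
      "type": "object",
      "required": ["id", "type"],
      "additionalProperties": false,
      "properties": {
        "id": { "type": "string" },
        "type": {
          "enum": ["instruction", "text", "number", "datetime", "slider",
                   "checkbox", "radio", "yesno", "media"]
        },
        "text": { "type": "string" },
        "required": { "type": "boolean", "default": false },
        "rand_group": { "type": "string" },
        "hide_id": { "type": "string" },
        "hide_value": { "type": ["string", "number", "boolean"] },
        "hide_if_matched": { "type": "boolean" },
        "min": { "type": "integer" },
        "max": { "type": "integer" },
        "hint_left": { "type": "string" },
        "hint_right": { "type": "string" },
        "options": {
          "type": "array", "minItems": 1,
          "items": { "type": "string" }, "uniqueItems": true
        },
        "subtype": { "enum": ["date", "time", "datetime", "image", "video", "audio"] },
        "src": { "type": "string" },
        "thumb": { "type": "string" }
      },
      "dependentRequired": {
        "hide_id": ["hide_value"],
        "hide_value": ["hide_id"]
      }
    },
    "graph": {
      "type": "object",
      "required": ["variable"],
      "additionalProperties": false,
      "properties": {
        "display": { "type": "boolean", "default": true },
        "variable": { "type": "string" },
        "title": { "type": "string" },
        "blurb": { "type": "string" },
        "type": { "enum": ["bar", "line"], "default": "line" },
        "max_points": { "type": "integer", "minimum": 1, "default": 10 }
      }
    }
  }
}
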