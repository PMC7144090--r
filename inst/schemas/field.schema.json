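{
  "$id": "blobr/field.schema.json",
  "title": "BlobDir field document",
  "description": "One JSON document per per-contig field. 'values' holds one entry per dataset identifier; category-valued fields additionally carry 'keys', an ordered list of labels indexed (0-based) by the values. Dynamic checks beyond this schema: value-array length equals the identifier count, category indices lie inside the keys list and variable metadata ranges cover the observed values.",
  "type": "object",
  "required": ["values"],
  "properties": {
    "values": {
      "type": "array",
      "items": {
        "oneOf": [
          {"type": "number"},
          {"type": "integer", "minimum": 0},
          {"type": "string"},
          {"type": "array"}
        ]
      }
    },
    "keys": {"type": "array", "items": {"type": "string"}}
  }
}
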