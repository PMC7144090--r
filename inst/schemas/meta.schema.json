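{
  "$id": "blobr/meta.schema.json",
  "title": "BlobDir metadata document",
  "description": "Collated dataset metadata: one entry under 'fields' per stored field document, so basic dataset information can be read without loading any values.",
  "type": "object",
  "required": ["id", "records", "fields"],
  "properties": {
    "id": {"type": "string"},
    "record_type": {"type": "string", "enum": ["contig", "scaffold"]},
    "records": {"type": "integer", "minimum": 1},
    "assembly": {"type": "object"},
    "taxon": {"type": "object"},
    "links": {"type": "object"},
    "settings": {"type": "object"},
    "fields": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "type", "datatype"],
        "properties": {
          "id": {"type": "string"},
          "type": {
            "type": "string",
            "enum": ["identifier", "variable", "category", "array", "multiarray"]
          },
          "datatype": {"type": "string", "enum": ["integer", "float", "string"]},
          "range": {"type": "array", "minItems": 2, "maxItems": 2},
          "preload": {"type": "boolean"},
          "scale": {"type": "string"},
          "parent": {"type": "string"},
          "children": {"type": "array", "items": {"type": "string"}}
        }
      }
    }
  }
}
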