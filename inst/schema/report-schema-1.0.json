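{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "epirelapse pipeline report",
  "version": "1.0",
  "type": "object",
  "required": [
    "schema_version",
    "package_version",
    "r_version",
    "seed",
    "config_hash",
    "partition",
    "dmp",
    "substructure_status",
    "fractions",
    "skipped_stages",
    "alpha",
    "pairing"
  ],
  "properties": {
    "schema_version": { "type": "string" },
    "package_version": { "type": "string" },
    "r_version": { "type": "string" },
    "seed": { "type": "integer" },
    "config_hash": { "type": "string" },
    "partition": { "type": "object" },
    "dmp": { "type": "object" },
    "substructure_status": { "type": "array" },
    "fractions": { "type": "array" },
    "cnv": { "type": "array" },
    "skipped_stages": { "type": "array" },
    "alpha": { "type": "number" },
    "pairing": { "type": "string" }
  }
}
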