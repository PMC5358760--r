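{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "pol3roadblock run report",
  "type": "object",
  "required": ["mode", "seed", "counts", "params", "version"],
  "properties": {
    "mode": { "type": "string", "enum": ["synthetic", "real"] },
    "seed": { "type": "integer" },
    "counts": { "type": "object" },
    "skipped": { "type": "array" },
    "params": { "type": "object" },
    "version": { "type": "string" }
  }
}
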