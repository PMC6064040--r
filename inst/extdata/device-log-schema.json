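{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "thyrowear intraday device-log document",
  "description": "One calendar day of intraday wearable data for one subject. Times are HH:MM (or HH:MM:SS for sub-minute sources; readers canonicalize to the minute grid by averaging heart-rate values and summing steps). Times must be strictly increasing with at most one sample per minute per array. A minute absent from steps_intraday means unknown activity (non-wear), which is distinct from an explicit value of 0.",
  "type": "object",
  "required": ["subject_id", "date", "heart_rate_intraday", "steps_intraday"],
  "properties": {
    "subject_id": { "type": "string" },
    "date": { "type": "string", "format": "date" },
    "heart_rate_intraday": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["time", "value"],
        "properties": {
          "time": { "type": "string", "pattern": "^\\d{2}:\\d{2}(:\\d{2})?$" },
          "value": { "type": "number", "minimum": 25, "maximum": 250 }
        }
      }
    },
    "steps_intraday": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["time", "value"],
        "properties": {
          "time": { "type": "string", "pattern": "^\\d{2}:\\d{2}(:\\d{2})?$" },
          "value": { "type": "number", "minimum": 0 }
        }
      }
    }
  }
}
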