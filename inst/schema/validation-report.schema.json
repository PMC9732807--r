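{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "snirf-validation-report/1.0",
  "title": "SNIRF validation report",
  "description": "Machine-readable compliance report produced by snirfio::reportToJson(). 'valid' is true iff no finding has severity FATAL or ERROR.",
  "type": "object",
  "required": ["schema", "valid", "findings"],
  "properties": {
    "schema": { "const": "snirf-validation-report/1.0" },
    "valid": { "type": "boolean" },
    "findings": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["code", "severity", "location", "message", "spec_ref"],
        "properties": {
          "code": {
            "type": "string",
            "enum": [
              "NOT_HDF5", "VERSION_MISSING", "VERSION_UNPARSEABLE",
              "NIRS_MISSING", "DATA_MISSING", "PROBE_MISSING", "NO_CHANNELS",
              "METADATA_MISSING", "LIST_LENGTH_MISMATCH",
              "INDEX_OUT_OF_RANGE", "DATA_TYPE_LABEL_MISSING",
              "UNKNOWN_DATA_TYPE", "TIME_LENGTH_MISMATCH",
              "TIME_NOT_INCREASING", "NONCONTIGUOUS_INDEX", "BAD_INDEX_NAME",
              "PROBE_DIM_MISMATCH", "POSITIONS_MISSING",
              "WAVELENGTHS_INVALID", "UNRECOGNIZED_CONTENT"
            ]
          },
          "severity": { "type": "string", "enum": ["FATAL", "ERROR", "WARNING", "INFO"] },
          "location": { "type": "string", "description": "Absolute HDF5 path of the offending object" },
          "message": { "type": "string" },
          "spec_ref": { "type": "string", "description": "Section anchor of the SNIRF format specification" }
        },
        "additionalProperties": false
      }
    }
  },
  "additionalProperties": false
}
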