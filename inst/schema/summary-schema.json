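{
  "version": "1.0",
  "description": "Structural schema for circuitseg pipeline summary.json",
  "required": [
    "schema_version",
    "seed",
    "bouton_labels",
    "no_split",
    "gap_nm",
    "projection",
    "capture",
    "class_counts"
  ],
  "properties": {
    "schema_version": "string",
    "seed": "integer",
    "bouton_labels": {"island": "integer", "nonisland": "integer", "ambiguous": "integer"},
    "no_split": "boolean",
    "gap_nm": {"median": "number", "min": "number", "max": "number", "no_zone": "boolean"},
    "projection": {"axis": "number[3]", "margin_nm": "number", "overlap_count": "integer"},
    "capture": {
      "n_tc": "integer",
      "n_eligible": "integer",
      "observed_captured": "integer",
      "captured_fraction": "number",
      "dendrite_counts": "integer[]",
      "thresholds": "object",
      "exact_mean": "number",
      "exact_tail": "number",
      "empirical_tail": "number"
    },
    "class_counts": "object"
  }
}
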