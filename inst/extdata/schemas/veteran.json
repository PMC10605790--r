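{
  "dataset": "Veteran",
  "description": "Veterans Administration lung cancer randomized-control trial; 137 subjects, 8 variables.",
  "time_col": "time",
  "event_col": "event",
  "binary": ["trt", "prior"],
  "categorical": ["celltype"],
  "continuous": ["age", "karno", "diagtime"]
}
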