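{
  "dataset": "GBCS",
  "description": "German Breast Cancer Study, node-positive primary breast cancer; 686 subjects, 16 variables.",
  "time_col": "time",
  "event_col": "event",
  "binary": ["menopause", "hormone"],
  "categorical": ["grade"],
  "continuous": ["age", "size", "nodes", "prog_recp", "estrg_recp"]
}
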