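{
  "dataset": "WHAS",
  "description": "Worcester Heart Attack Study, acute myocardial infarction admissions; 481 subjects, 14 variables.",
  "time_col": "time",
  "event_col": "event",
  "binary": ["sex", "sho", "chf", "miord"],
  "categorical": ["mitype", "yrgrp"],
  "continuous": ["age", "ckp"]
}
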