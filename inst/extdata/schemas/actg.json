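{
  "dataset": "ACTG",
  "description": "AIDS Clinical Trials Group HIV randomized-control trial; 1151 subjects, 16 variables. Column kinds from the published variable list.",
  "time_col": "time",
  "event_col": "event",
  "binary": ["sex", "hemophil"],
  "categorical": ["strat2", "txgrp", "ivdrug", "karnof", "raceth"],
  "continuous": ["age", "cd4", "priorzdv"]
}
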