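{
  "dataset": "PBC",
  "description": "Primary biliary cirrhosis D-penicillamine randomized-control trial; 418 subjects, 20 variables.",
  "time_col": "time",
  "event_col": "event",
  "binary": ["sex", "trt", "ascites", "hepatomegaly", "spiders"],
  "categorical": ["edema", "histologic"],
  "continuous": ["age", "bilirubin", "cholesterol", "albumin", "copper", "alkphosphotase", "sgot", "triglycerides", "platelet", "prothrombin"]
}
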