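{
  "N": [100, 500],
  "p": [6],
  "thresholds": [1, 2],
  "loading": [0.6, 0.9],
  "skew_pattern": ["None", "SM"]
}
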