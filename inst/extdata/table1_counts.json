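{
  "n_patients": 55,
  "n_hemangiomas": 55,
  "n_positive": 48,
  "n_negative": 0,
  "n_null": 7
}
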