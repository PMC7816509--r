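{
  "aspirational": {
    "bursting_kpa": 700,
    "snag_n": 200,
    "abrasion_rubs": 400,
    "hole_score_max": 100
  },
  "pi_value": 3.142
}
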