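{
  "name": "slow",
  "comment": "slow SNr response",
  "overrides": {"vmax_sert": 433, "vmax_u2": 1400, "gate_lo": 55, "gate_hi": 65,
                "s_rel": 1.25, "s_syn": 0.25, "s_ha": 2},
  "r": 4.5
}
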