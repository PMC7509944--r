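{
  "name": "hybrid",
  "comment": "hybrid SNr response",
  "overrides": {"vmax_sert": 433, "vmax_u2": 5600, "gate_lo": 52, "gate_hi": 62,
                "s_rel": 1.25, "s_syn": 0.25, "s_ha": 3},
  "r": 22
}
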