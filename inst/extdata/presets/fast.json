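{
  "name": "fast",
  "comment": "fast SNr response; inhibsyn slope (.2)(12.5) as published",
  "overrides": {"vmax_sert": 433, "vmax_u2": 3220, "gate_lo": 40, "gate_hi": 50,
                "s_rel": 2.5, "s_syn": 2.5, "s_ha": 5},
  "r": 10.3
}
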