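{
  "name": "male",
  "comment": "fitted average male hippocampal CA2 response",
  "overrides": {"vmax_u2": 1680, "gate_lo": 60.5, "gate_hi": 75.5,
                "s_rel": 10, "beta1": 0.8, "beta2": 0.6, "beta3": 0.8},
  "r": 18
}
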