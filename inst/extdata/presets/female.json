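{
  "name": "female",
  "comment": "fitted average female hippocampal CA2 response",
  "overrides": {"vmax_u2": 1680, "gate_lo": 60.5, "gate_hi": 70.5,
                "s_rel": 12.5, "beta1": 0.85, "beta2": 0.7, "beta3": 0.85},
  "r": 18.5
}
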