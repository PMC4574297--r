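{
  "scenario": "baseline",
  "solver": {"n_nodes": 101},
  "outputs": "mitoconstrict-out",
  "emit_shapes": true,
  "emit_curve": true,
  "Pi_max": 25,
  "log_level": "info"
}
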