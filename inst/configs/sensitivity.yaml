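# LHS/PRCC sensitivity of the treated/control tumor ratio (well-mixed surrogate)
command: sensitivity
seed: 1
parameters: defaults
sensitivity: {n: 5000, factor: 2, eval_time: 15, mode: wellmixed}
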