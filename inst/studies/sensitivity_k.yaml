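study: sensitivity
name: sensitivity_k
gate: tetr_ptet
model: constant_cv
varied: k
n_cells: 10000
seed: 1
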