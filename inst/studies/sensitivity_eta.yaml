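study: sensitivity
name: sensitivity_eta
gate: tetr_ptet
model: constant_cv
varied: eta
n_cells: 10000
seed: 1
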