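study: characterize
name: yes_gate_constant_var
gate: yes_gate
model: constant_var
entities: [0.05, 0.1, 0.15]
n_cells: 10000
seed: 1
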