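study: extrinsic
name: extrinsic_sweep
gate: tetr_ptet
model: constant_cv
entities: [0.15, 0.55, 0.75]
output2_level: 0.15
rho_values: [0, 0.25, 0.5, 0.75, 1]
n_cells: 10000
seed: 1
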