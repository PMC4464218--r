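study: blackbox_reference
name: blackbox_reference
seed: 1
grid_points: 50
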