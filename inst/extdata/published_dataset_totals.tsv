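quantity	value
n_ghsr_pos	16425
n_cnr1_pos	1648932
n_double_pos	9554
pct_double_neuron	99.8
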