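name,amount_per_cell_amol,c1_per_molecule
ATP,46,2
GTP,14,2
dATP,3,2
dGTP,3,2
dTTP,3,1
histidine,9,1
methionine,48,1
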