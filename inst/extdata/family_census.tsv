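quantity	value
lrr_containing_sequences	7767
no_lrr_sequences	593
outgroup_phypa	134
outgroup_selml	81
complex_og_genes	2956
complex_og_count	24
noncomplex_og_genes	3783
noncomplex_og_count	77
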