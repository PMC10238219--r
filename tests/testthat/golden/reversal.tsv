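label	n_genes	n_dysregulated	n_reversed	reversed_fraction	n_perturbation_affected	pvalue	padj	median_disease_sign	median_perturbation_lfc	call
0	6	5	5	1	6	0.0497737556561086	0.0746606334841629	-1	3.2049057290396	unchanged
1	6	6	6	1	6	0.0497737556561086	0.0746606334841629	1	-3.22407988554241	unchanged
2	6	5	0	0	0	1	1	1	-0.378281091397223	unchanged
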