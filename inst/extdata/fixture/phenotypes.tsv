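feature	control_1	control_2	control_3	d7_1	d7_2	d7_3	d14_1	d14_2	d14_3	d21_1	d21_2	d21_3	d28_1	d28_2	d28_3
pheno_pos	0	0	0	-1.5	-1.5	-1.5	-2	-2	-2	-1.5	-1.5	-1.5	-1	-1	-1
pheno_neg	-0.288580024775965	-0.08775771686354	0.0776364648723754	-2.34563956577454	-1.94126515211409	-1.99096281661951	-1.97437468051632	-1.66501693618542	-2.3656572246734	-0.619789383373034	-1.22343447884054	-1.33936557125072	-0.714907547009893	-0.424204289106136	-0.454386288003321
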