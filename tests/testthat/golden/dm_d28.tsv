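feature	log2fc	pvalue	padj	contrast
met002	-1.54535817364311	0.000255237728895609	0.000701903754462925	d28_vs_control
met003	-1.22750525282514	0.000235371039223608	0.000701903754462925	d28_vs_control
met004	0.520658295103775	0.0219979499591661	0.0345682070786896	d28_vs_control
met005	1.11473194706583	0.00604253110574126	0.011077973693859	d28_vs_control
met006	0.208930549309018	0.222297163363654	0.305658599625025	d28_vs_control
met007	1.01823899023155	5.42558234820995e-05	0.000298407029151547	d28_vs_control
met008	1.63434682738793	0.000542405409634442	0.00119329190119577	d28_vs_control
met009	3.00150958775367	3.09309466748336e-06	3.4024041342317e-05	d28_vs_control
met010	-0.0437753339456403	0.790104675670156	0.864910056054826	d28_vs_control
met011	0.0135312574977316	0.864910056054826	0.864910056054826	d28_vs_control
met012	0.0448891752536787	0.786949139514135	0.864910056054826	d28_vs_control
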