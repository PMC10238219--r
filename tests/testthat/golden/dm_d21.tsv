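feature	log2fc	pvalue	padj	contrast
met002	-2.3132646889538	0.00011830668440144	0.000433087319968598	d21_vs_control
met003	-1.6589760331663	0.000157486298170399	0.000433087319968598	d21_vs_control
met004	1.09983349157602	0.00234377831849839	0.00368308021478318	d21_vs_control
met005	2.13931873702074	0.000252679343310215	0.000555894555282472	d21_vs_control
met006	0.8016909422679	0.00341875602484114	0.00470078953415657	d21_vs_control
met007	1.30652621352716	1.08611925948409e-05	5.9736559271625e-05	d21_vs_control
met008	1.55537268749472	0.00082522808062589	0.00151291814781413	d21_vs_control
met009	2.9811120926396	6.28706682580871e-06	5.9736559271625e-05	d21_vs_control
met010	0.0477221242071959	0.724637287867353	0.797101016654088	d21_vs_control
met011	0.0389042075657985	0.714805306111111	0.797101016654088	d21_vs_control
met012	-0.0304833853576076	0.855135999664184	0.855135999664184	d21_vs_control
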