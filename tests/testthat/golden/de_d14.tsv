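feature	log2fc	pvalue	padj	contrast
gene0001	-3.96024051667178	0.00292721855923122	0.0109770695971171	d14_vs_control
gene0002	-3.60232007665054	0.000601537708995377	0.00725190474456338	d14_vs_control
gene0003	-3.59564790109285	0.00975322092704739	0.0225074329085709	d14_vs_control
gene0004	-3.2408007472199	0.00173643356153447	0.00769866399211702	d14_vs_control
gene0005	-3.60897323767033	0.00774609298054881	0.019365232451372	d14_vs_control
gene0006	-2.54342422254235	0.010997262326667	0.0235655621285722	d14_vs_control
gene0007	3.00181427885096	0.0281443929562228	0.0527707367929178	d14_vs_control
gene0008	3.45705937205952	0.000508515782451761	0.00725190474456338	d14_vs_control
gene0009	0.460100439772647	0.326709138247799	0.363010153608666	d14_vs_control
gene0010	3.4594180871078	0.00120865079076056	0.00725190474456338	d14_vs_control
gene0011	1.38254268515586	0.0816772107600937	0.116681729657277	d14_vs_control
gene0012	2.79554880198552	0.00100255455535907	0.00725190474456338	d14_vs_control
gene0013	1.635870690442	0.0474395825005443	0.0837169102950782	d14_vs_control
gene0014	1.59156422580934	0.0066166957329388	0.019365232451372	d14_vs_control
gene0015	2.06993934237715	0.00105354213903109	0.00725190474456338	d14_vs_control
gene0016	2.86804710937528	0.00179635493149397	0.00769866399211702	d14_vs_control
gene0017	3.75730186172687	0.00760310108190633	0.019365232451372	d14_vs_control
gene0018	1.42816307314963	0.0215722368304585	0.0431444736609169	d14_vs_control
gene0019	0.048830702612765	0.863126908010399	0.863126908010399	d14_vs_control
gene0020	-1.00687570216003	0.0510479599455954	0.085079933242659	d14_vs_control
gene0021	-1.21137353908338	0.0675380191604613	0.101307028740692	d14_vs_control
gene0022	-0.815761536496665	0.0567193376337109	0.089556848895333	d14_vs_control
gene0023	-0.278790121247671	0.562592606381496	0.581992351429134	d14_vs_control
gene0024	-0.48104472122325	0.287182333753942	0.331364231254549	d14_vs_control
gene0025	-0.589872831281773	0.207560161852599	0.259450202315749	d14_vs_control
gene0026	-0.313119102498042	0.205009342463571	0.259450202315749	d14_vs_control
gene0027	-0.337674762314522	0.238468452402258	0.286162142882709	d14_vs_control
gene0028	-1.57233472992808	0.00334212948244879	0.0111404316081626	d14_vs_control
gene0029	-0.730786558994979	0.11580084507794	0.1579102432881	d14_vs_control
gene0030	0.393761722083525	0.542413061059396	0.581156851135067	d14_vs_control
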