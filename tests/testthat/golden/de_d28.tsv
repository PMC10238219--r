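feature	log2fc	pvalue	padj	contrast
gene0001	-2.36829332065256	0.00153950397273681	0.02377972286014	d28_vs_control
gene0002	-1.78478242667174	0.00808930054992216	0.036128546760703	d28_vs_control
gene0003	-1.88530608316974	0.00859093326907926	0.036128546760703	d28_vs_control
gene0004	-1.24978314127059	0.0767918876989581	0.191979719247395	d28_vs_control
gene0005	-0.75065271114138	0.0125399485138762	0.0417998283795874	d28_vs_control
gene0006	-1.72379592542223	0.0273078344960048	0.0744759122618314	d28_vs_control
gene0007	1.5256271543757	0.144726191099466	0.309407555944165	d28_vs_control
gene0008	1.15706143065191	0.0220950152852351	0.0662850458557053	d28_vs_control
gene0009	-0.256578156208452	0.507639915513804	0.634549894392255	d28_vs_control
gene0010	0.356547541674118	0.442119435753378	0.631599193933397	d28_vs_control
gene0011	0.343080175205348	0.505636081404565	0.634549894392255	d28_vs_control
gene0012	0.342946775488215	0.286840927684167	0.478068212806945	d28_vs_control
gene0013	1.85790782505021	0.00888362709530831	0.036128546760703	d28_vs_control
gene0014	1.28494487463553	0.00299821973932304	0.0299821973932304	d28_vs_control
gene0015	1.68122724667565	0.00633523758615848	0.036128546760703	d28_vs_control
gene0016	3.1714831137976	0.00158531485734267	0.02377972286014	d28_vs_control
gene0017	3.18914983239006	0.00963427913618748	0.036128546760703	d28_vs_control
gene0018	0.764857068674084	0.170811902544752	0.320272317271411	d28_vs_control
gene0019	0.0218204605627204	0.9352521405537	0.972985095697609	d28_vs_control
gene0020	-0.27931755942191	0.503317372560029	0.634549894392255	d28_vs_control
gene0021	-0.0488650444716576	0.940552259174356	0.972985095697609	d28_vs_control
gene0022	-0.346732037581315	0.217029928531977	0.382993991527019	d28_vs_control
gene0023	-0.00426643705000984	0.99388034771335	0.99388034771335	d28_vs_control
gene0024	-0.664271315430706	0.154703777972083	0.309407555944165	d28_vs_control
gene0025	-0.166453136233399	0.660025854773476	0.761568293969395	d28_vs_control
gene0026	-0.186335465752961	0.422801423796629	0.631599193933397	d28_vs_control
gene0027	-0.216557593740225	0.124101959944235	0.286389138332851	d28_vs_control
gene0028	-0.0716813462159314	0.566183059229685	0.679419671075622	d28_vs_control
gene0029	-0.626781265559276	0.303080146851211	0.478547600291385	d28_vs_control
gene0030	0.239726193350418	0.725197649515076	0.805775166127862	d28_vs_control
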