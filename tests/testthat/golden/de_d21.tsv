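feature	log2fc	pvalue	padj	contrast
gene0001	-3.2777127304774	0.00618408836689657	0.0448944725306397	d21_vs_control
gene0002	-2.35352212551778	0.0122322673544783	0.0448944725306397	d21_vs_control
gene0003	-3.3479710279869	0.0228515252000772	0.0527342889232552	d21_vs_control
gene0004	-2.2887100808479	0.0116767371833382	0.0448944725306397	d21_vs_control
gene0005	-2.08072761368872	0.071426925637593	0.142853851275186	d21_vs_control
gene0006	-1.96674257709353	0.0134683417591919	0.0448944725306397	d21_vs_control
gene0007	1.66111140681281	0.121520226995863	0.202533711659772	d21_vs_control
gene0008	2.29766030769074	0.00177007120751452	0.03755436169686	d21_vs_control
gene0009	0.318711288095679	0.494400449741921	0.593280539690305	d21_vs_control
gene0010	1.9752005398088	0.00865926989944935	0.0448944725306397	d21_vs_control
gene0011	0.488885451510066	0.367167031024788	0.550750546537183	d21_vs_control
gene0012	1.18464960929185	0.10047537191839	0.177309479855983	d21_vs_control
gene0013	1.88981458462487	0.00875334638248063	0.0448944725306397	d21_vs_control
gene0014	1.65333045015674	0.0131049205148823	0.0448944725306397	d21_vs_control
gene0015	1.47958852366675	0.002503624113124	0.03755436169686	d21_vs_control
gene0016	1.76541855011686	0.0161874758350702	0.0480452829468946	d21_vs_control
gene0017	3.63745875357084	0.0192181131787578	0.0480452829468946	d21_vs_control
gene0018	0.840690835872003	0.094030102891726	0.176306442921986	d21_vs_control
gene0019	-0.427870382269541	0.182830773540163	0.288680168747625	d21_vs_control
gene0020	0.153102634908388	0.682158767424895	0.730884393669531	d21_vs_control
gene0021	-0.32391886777911	0.628652880540453	0.725368708315907	d21_vs_control
gene0022	-0.888757985396191	0.053872013540429	0.115440029015205	d21_vs_control
gene0023	0.0104842586119807	0.981742982803692	0.981742982803692	d21_vs_control
gene0024	-0.27088851598656	0.488415309389927	0.593280539690305	d21_vs_control
gene0025	-0.177240070919932	0.676819401409063	0.730884393669531	d21_vs_control
gene0026	-0.251818635325562	0.481150303067844	0.593280539690305	d21_vs_control
gene0027	-0.491220003516942	0.39969207612854	0.570988680183628	d21_vs_control
gene0028	-0.688419420166743	0.0179248623687455	0.0480452829468946	d21_vs_control
gene0029	-0.345715752039066	0.471973425282955	0.593280539690305	d21_vs_control
gene0030	-0.136183319975431	0.876087289716161	0.906297196258098	d21_vs_control
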