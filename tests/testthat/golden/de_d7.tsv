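feature	log2fc	pvalue	padj	contrast
gene0001	-3.55393239472284	0.00601998880861446	0.0250844424409381	d7_vs_control
gene0002	-2.00326215855726	0.00559468116296662	0.0250844424409381	d7_vs_control
gene0003	-2.83554597205496	0.016005504707138	0.0436513764740127	d7_vs_control
gene0004	-2.80982287167696	0.00542222652986657	0.0250844424409381	d7_vs_control
gene0005	-1.98926772010789	0.0118521115035068	0.0355563345105203	d7_vs_control
gene0006	-2.44938938489203	0.00668918465091682	0.0250844424409381	d7_vs_control
gene0007	3.12809577802923	0.0250283471916956	0.0625708679792389	d7_vs_control
gene0008	3.91661348116046	0.00104824588113829	0.0167106520786498	d7_vs_control
gene0009	1.19009496114144	0.0567265557490548	0.106362292029478	d7_vs_control
gene0010	3.32745264366926	0.00167106520786498	0.0167106520786498	d7_vs_control
gene0011	1.44613780366339	0.0976152165997097	0.154129289367963	d7_vs_control
gene0012	3.0180386946694	0.00122600035546082	0.0167106520786498	d7_vs_control
gene0013	0.493229770959779	0.352014915001776	0.502878450002537	d7_vs_control
gene0014	1.03264853227331	0.0765626093903267	0.1351104871594	d7_vs_control
gene0015	1.38280276496952	0.00352074293796933	0.0250844424409381	d7_vs_control
gene0016	1.74061224498027	0.0110618937394481	0.0355563345105203	d7_vs_control
gene0017	1.95086404600818	0.0433031128292363	0.0927923846340779	d7_vs_control
gene0018	0.863291804128206	0.0815008419926563	0.135834736654427	d7_vs_control
gene0019	-0.83599671495316	0.0414178137415146	0.0927923846340779	d7_vs_control
gene0020	-0.196581161625128	0.653506732799248	0.754046230152978	d7_vs_control
gene0021	-0.45494787649403	0.434248618627664	0.566411241688257	d7_vs_control
gene0022	-0.0972631239585109	0.764982659561795	0.849980732846438	d7_vs_control
gene0023	-0.24607490264683	0.52555253370476	0.630663040445712	d7_vs_control
gene0024	0.0118215256118193	0.97387405046784	0.97387405046784	d7_vs_control
gene0025	0.0653440818817685	0.891983096990294	0.955696175346744	d7_vs_control
gene0026	-0.766155705231465	0.0493925834232985	0.0987851668465969	d7_vs_control
gene0027	-0.0251200080937144	0.945187432323906	0.97387405046784	d7_vs_control
gene0028	-0.442559574953241	0.410753341344491	0.560118192742487	d7_vs_control
gene0029	-0.462720677043345	0.2635912678632	0.395386901794799	d7_vs_control
gene0030	0.438719337426328	0.509000394870818	0.630663040445712	d7_vs_control
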