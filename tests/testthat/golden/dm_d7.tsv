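feature	log2fc	pvalue	padj	contrast
met002	-2.40595763799993	0.000102248404489141	0.00037825973975532	d7_vs_control
met003	-1.55135055442474	0.000137548996274662	0.00037825973975532	d7_vs_control
met004	2.3646357876648	0.000594701806241022	0.00109028664477521	d7_vs_control
met005	4.1789025754179	0.000129816833165951	0.00037825973975532	d7_vs_control
met006	1.79609585207014	0.00138411158824285	0.00217503249581019	d7_vs_control
met007	0.630580659478603	0.00841635603202776	0.0115724895440382	d7_vs_control
met008	1.38440666844573	0.000289048357740805	0.000635906387029772	d7_vs_control
met009	1.86493434986268	6.95574950870399e-06	7.65132445957439e-05	d7_vs_control
met010	-0.117470967704052	0.438699981432082	0.508443275630671	d7_vs_control
met011	0.0766046658550904	0.462221159664246	0.508443275630671	d7_vs_control
met012	0.0255571418958761	0.872145192927137	0.872145192927137	d7_vs_control
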