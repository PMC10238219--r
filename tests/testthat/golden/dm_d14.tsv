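feature	log2fc	pvalue	padj	contrast
met002	-3.0030447780016	7.54053179509526e-05	0.000322154116470492	d14_vs_control
met003	-2.08904339100397	8.78602135828615e-05	0.000322154116470492	d14_vs_control
met004	2.53827501910271	0.00112750877665738	0.00177179950617589	d14_vs_control
met005	4.173165833304	0.000180750064878419	0.000497062678415651	d14_vs_control
met006	1.76874903626027	0.002879884684438	0.00395984144110225	d14_vs_control
met007	1.7008175813391	0.000610631194517481	0.00111949052328205	d14_vs_control
met008	2.12398353343865	1.79696484407483e-06	1.97666132848231e-05	d14_vs_control
met009	3.82622834371604	0.000536770104565381	0.00111949052328205	d14_vs_control
met010	-0.130655569025233	0.375888240990576	0.459418961210705	d14_vs_control
met011	0.0345413850710038	0.767321500238955	0.767321500238955	d14_vs_control
met012	0.111321673684101	0.464618760297554	0.51108063632731	d14_vs_control
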