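source	target	rho	p	fdr
met002	met003	0.9	4.87197094873564e-06	4.46597336967434e-05
met002	met004	-0.907142857142857	3.0633105354939e-06	3.36964158904329e-05
met003	met004	-0.864285714285714	3.2433731433468e-05	0.000254836461262963
met002	met005	-0.853571428571429	5.17314356670973e-05	0.000355653620211294
met003	met005	-0.785714285714286	0.000516454747570588	0.00202892936545588
met004	met005	0.946428571428571	9.44793851035239e-08	5.19636618069382e-06
met002	met006	-0.839285714285714	9.13693584651998e-05	0.000502531471558599
met003	met006	-0.810714285714286	0.000246007977972205	0.00104080298372856
met004	met006	0.939285714285714	2.09458019366857e-07	5.51951697256802e-06
met005	met006	0.935714285714286	3.01064562140074e-07	5.51951697256802e-06
met002	met007	-0.714285714285714	0.00277438381763881	0.00953694437313341
met003	met007	-0.832142857142857	0.000119028244938498	0.000595141224692491
met002	met008	-0.678571428571428	0.00541655021959171	0.0175241330633849
met003	met008	-0.675	0.00576349921805083	0.0176106920551553
met007	met008	0.825	0.000153235570905647	0.000702329699984215
met002	met009	-0.639285714285714	0.0102884466195942	0.0297823454777726
met003	met009	-0.760714285714286	0.000991128611982373	0.00363413824393537
met007	met009	0.925	7.9874621138185e-07	1.09827604065004e-05
met008	met009	0.846428571428571	6.92382360973721e-05	0.000423122553928385
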