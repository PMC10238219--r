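source	target	rho	p	fdr
gene0003	gene0004	0.8	0.000342269833035693	0.00446752203120273
gene0001	gene0005	0.803571428571428	0.000307265031812509	0.0043543844508287
gene0004	gene0005	0.860714285714286	3.80552502266473e-05	0.00134103095888263
gene0004	gene0006	0.803571428571428	0.000307265031812509	0.0043543844508287
gene0007	gene0008	0.892857142857143	7.49473606456829e-06	0.000549002625399099
gene0007	gene0010	0.814285714285714	0.000219365827727103	0.00350985324363364
gene0008	gene0010	0.892857142857143	7.49473606456829e-06	0.000549002625399099
gene0008	gene0012	0.917857142857143	1.41769685150064e-06	0.000351588819172159
gene0010	gene0012	0.871428571428571	2.32364778216326e-05	0.000960441083294147
gene0001	pheno_pos	0.889950154893794	8.85488105482418e-06	0.000549002625399099
gene0002	pheno_pos	0.856367130180821	4.59627546391224e-05	0.00134103095888263
gene0003	pheno_pos	0.822784105467848	0.000165354144010005	0.00315444828572932
gene0004	pheno_pos	0.889950154893794	8.85488105482418e-06	0.000549002625399099
gene0005	pheno_pos	0.940324691963254	1.87703893400865e-07	9.31011311268293e-05
gene0006	pheno_pos	0.805992593111361	0.000285243926216851	0.00428730264859268
gene0007	pheno_pos	-0.783603909969379	0.000547408173974436	0.00631428963468187
gene0008	pheno_pos	-0.839575617824334	9.03699893308035e-05	0.00213445308133707
gene0010	pheno_pos	-0.884352984108299	1.20548306667291e-05	0.000664355112299738
gene0011	pheno_pos	-0.677257665044963	0.00554220087370644	0.0340320906208716
gene0012	pheno_pos	-0.833978447038839	0.000111338148040489	0.00240103136643837
gene0015	pheno_pos	-0.722035031328927	0.00236896392281817	0.0183052086776304
gene0018	pheno_pos	-0.755618056041901	0.00112148316256739	0.0106972240121812
gene0028	pheno_pos	0.778006739183883	0.000636882956345294	0.00701986547438368
gene0001	pheno_neg	0.764285714285714	0.000907310111684976	0.00918420031419894
gene0002	pheno_neg	0.667857142857143	0.00650995669471544	0.0366924831883961
gene0003	pheno_neg	0.717857142857143	0.00258116530821886	0.0191083282518888
gene0004	pheno_neg	0.864285714285714	3.2433731433468e-05	0.0012374715993077
gene0005	pheno_neg	0.807142857142857	0.00027524427069542	0.00426628619577902
gene0006	pheno_neg	0.782142857142857	0.000569709627773496	0.00642218125853759
gene0007	pheno_neg	-0.871428571428571	2.32364778216326e-05	0.000960441083294147
gene0008	pheno_neg	-0.903571428571428	3.88050412879976e-06	0.00048118251197117
gene0010	pheno_neg	-0.857142857142857	4.44600444700478e-05	0.00134103095888263
gene0011	pheno_neg	-0.685714285714286	0.00477224522269125	0.0307406964994138
gene0012	pheno_neg	-0.853571428571429	5.17314356670973e-05	0.00135046274162528
gene0018	pheno_neg	-0.696428571428571	0.00392119050687955	0.0259321398854968
pheno_pos	pheno_neg	0.856367130180821	4.59627546391224e-05	0.00134103095888263
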