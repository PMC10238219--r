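feature	control_1	control_2	control_3	d7_1	d7_2	d7_3	d14_1	d14_2	d14_3	d21_1	d21_2	d21_3	d28_1	d28_2	d28_3
met001	9.06452390402575	8.81962466170748	7.53014989028073	2.06973342184643					1.59194703240454		2.83824082191592				3.51956028002813
met002	25.2310581039934	24.9467917001405	29.2302441375312		5.22659533441974	4.76208455207884		3.10290792555995	3.50048220164998	5.84490241137756	4.74128574371943	5.39108691987595	9.31907998473508	8.42208623056571	9.46489101645351
met003	121.137619644306	109.449337021893	104.594892777609	35.9337845776611	37.4270246368723	41.0000585971305	23.8310884735031	24.6094809344041	30.3393931416631	31.2361492357857	35.0110824259503	39.8927345113483	45.029231103311	50.0165026791807	48.0954458785876
met004	5.75248389798087	6.30415256589139	7.91465709779997	39.5409070913535	32.923966079352	30.3918054821518	31.4344297338374	44.1924312710809	40.3851923050837	12.8384414410087	15.9213235430119	14.0446993641206	9.11351666989924	9.06743421122864	10.4700606737405
met005	21.7303969935527	17.1514156612556	17.9789183902807	387.206956054705	315.105900199059	327.569132935202	297.011025352557	379.565944199345	349.217921443061	85.7445655943945	73.824756418179	90.9328807516124	47.4074669574124	41.8121258198543	33.9150322515563
met006	27.8793270605069	21.6034761478339	22.7220509589889	95.9978857393303	83.9489806657327	70.8055470524998	71.6543454701854	99.2888225755337	75.1009061975987	44.6069022214175	43.5255156042858	37.7309696269886	25.5001344016069	26.7405293770748	31.215949641491
met007	40.7904712750895	34.30725168992	40.0263738910634	56.8004946318323	66.9672151678471	54.4660339329447	137.650723517745	108.488743692915	128.111856700516	95.6488132186576	94.4623019964299	94.6428737483274	77.4572306030393	79.086022339156	76.6342864053459
met008	12.368233079611	14.4405977473215	14.0191632789964	37.6400434743296	32.0862950663245	36.861088030301	59.7608668997528	57.6565016049872	60.5501714640344	35.0102466695883	40.1209255640602	44.8662389685947	47.2904630263738	37.7532818241444	41.7055236985771
met009	153.269478101744	138.181459478994	134.376454349946	504.895586165592	538.772723396743	507.413747114421	1845.66828659214	1811.87983068277	2382.53752204967	1177.34839230241	1113.73304095977	1071.228587275	1162.8490374749	1084.61527295605	1162.72126271503
met010	16.4702738461279	17.0570179864155	21.4954895220686	17.761433761795	15.966646462016	16.9920377373249	16.4626960744106	17.0501853597208	16.7458236090446	19.7126873775344	18.4710365132156	18.6895633156137	19.0144309260543	15.6124576318428	18.7514253355247
met011	33.0119982203919	29.3499877221728	28.8302748609947	32.0813296647129	34.7438290183265	29.3401178799429	33.9570568140288	31.9712383605934	27.47366179156	33.8134138553277	28.1339720239521	31.7374534140857	30.6715837334092	32.2031797988995	29.176827029428
met012	55.1863946119144	44.0727844787331	60.9055515275317	49.3902613898339	57.9124133788838	55.7246319741646	55.0263719862626	61.4145488822217	56.5718057752759	57.9971460372466	48.5218788113275	50.2970121311722	55.3756841189584	60.3049187029996	49.5459628353756
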