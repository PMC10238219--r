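feature	control_1	control_2	control_3	d7_1	d7_2	d7_3	d14_1	d14_2	d14_3	d21_1	d21_2	d21_3	d28_1	d28_2	d28_3
gene0001	58	68	125	16	11	5	9	4	12	6	14	13	19	24	14
gene0002	243	123	282	58	100	89	22	37	27	48	98	34	84	75	64
gene0003	65	65	78	27	10	11	10	13	5	9	4	16	13	33	28
gene0004	725	565	879	242	127	136	88	153	163	310	201	130	322	696	239
gene0005	111	99	128	56	55	28	20	8	20	76	40	15	72	83	98
gene0006	81	33	81	13	16	22	14	15	23	30	16	18	30	23	16
gene0007	363	77	137	1195	2364	3751	1684	3855	1627	441	803	920	571	465	700
gene0008	193	175	169	3637	3464	6440	2742	4050	3641	1577	981	1177	555	513	450
gene0009	277	330	236	968	1002	1083	608	879	557	350	651	489	235	351	308
gene0010	90	122	90	1446	2570	1120	1463	2405	2018	813	401	498	174	215	112
gene0011	379	927	1232	3932	5765	1579	1815	3825	5855	1290	1735	1422	831	1619	1321
gene0012	266	152	371	3854	3347	2542	2093	3453	3702	1500	521	602	289	473	451
gene0013	64	42	130	131	271	113	244	689	337	426	442	257	320	435	246
gene0014	18	12	23	41	53	85	67	84	139	55	103	79	48	55	59
gene0015	342	456	610	1636	1887	2236	3703	2525	3997	2037	1450	1862	2008	1697	1857
gene0016	155	75	146	592	576	768	1045	1702	1996	379	676	701	1355	1672	1120
gene0017	174	52	95	404	752	680	3042	1874	2019	1723	1792	1460	644	2276	915
gene0018	495	505	400	1703	1131	1278	1657	2011	3102	911	1202	1397	639	1916	807
gene0019	173	270	371	212	208	280	466	516	422	311	223	272	269	338	401
gene0020	304	148	287	418	226	370	164	179	284	308	360	426	151	275	349
gene0021	214	486	392	340	689	275	273	264	239	443	669	186	175	780	542
gene0022	196	302	385	494	528	291	312	195	361	214	164	270	208	379	282
gene0023	171	77	149	187	158	162	197	113	260	274	142	137	226	134	129
gene0024	25	19	17	34	37	27	31	18	27	24	20	25	12	16	20
gene0025	178	161	471	315	335	598	260	195	411	303	409	200	182	309	341
gene0026	95	101	106	121	73	94	109	143	179	87	165	111	79	126	139
gene0027	92	76	110	146	219	93	141	91	156	50	141	103	80	118	104
gene0028	32	32	44	24	47	63	20	16	25	27	34	30	30	54	48
gene0029	82	41	111	102	91	62	58	83	88	91	112	47	28	117	61
gene0030	153	201	88	416	250	266	330	340	291	199	367	74	266	191	177
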