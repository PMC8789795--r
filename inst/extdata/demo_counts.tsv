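gene	ex_rich	mem_rich	cold
mkN01	139	104	0
mkN02	45	66	0
mkN03	148	160	0
mkN04	43	38	0
mkA01	157	128	0
mkA02	44	41	0
mkA03	95	111	0
mkA04	80	66	0
mkEX01	753	237	0
mkEX02	297	90	0
mkEX03	317	88	0
mkEX04	360	103	0
mkEM01	396	1130	0
mkEM02	272	870	0
mkEM03	218	614	0
mkEM04	266	728	0
mkCM01	145	129	0
mkCM02	150	143	0
mkCM03	79	76	0
mkCM04	48	36	0
null0001	1930	1945	4334
null0002	297	320	729
null0003	916	852	1132
null0004	448	461	1014
null0005	1985	1982	3464
null0006	1294	1357	2114
null0007	1406	1434	2803
null0008	888	867	1622
null0009	478	482	535
null0010	796	811	657
null0011	340	361	294
null0012	330	317	237
null0013	677	666	476
null0014	111	104	117
null0015	99	87	54
null0016	952	917	503
null0017	426	384	233
null0018	247	246	109
null0019	122	118	195
null0020	105	89	114
null0021	1120	1123	925
null0022	75	84	46
null0023	459	460	347
null0024	514	510	908
null0025	259	243	120
null0026	492	511	318
null0027	1100	1124	813
null0028	293	271	231
null0029	130	128	142
null0030	85	96	80
null0031	88	79	98
null0032	67	66	107
null0033	182	197	101
null0034	275	311	123
null0035	553	516	572
null0036	259	254	230
null0037	312	331	189
null0038	122	116	113
null0039	194	212	104
null0040	109	69	63
null0041	163	153	122
null0042	167	174	88
null0043	172	172	106
null0044	224	211	182
null0045	184	187	111
null0046	310	270	173
null0047	835	796	780
null0048	358	339	347
null0049	409	376	380
null0050	567	551	357
null0051	536	527	416
null0052	194	171	118
null0053	502	460	694
null0054	354	364	148
null0055	315	300	368
null0056	123	127	95
null0057	274	301	378
null0058	251	258	326
null0059	233	221	307
null0060	68	87	85
null0061	145	142	193
null0062	1820	1759	899
null0063	98	76	142
null0064	176	175	200
null0065	793	776	896
null0066	364	287	373
null0067	2368	2346	2907
null0068	453	411	281
null0069	413	373	243
null0070	1929	1856	1402
null0071	243	253	247
null0072	147	168	85
null0073	154	182	224
null0074	432	451	210
null0075	1906	1811	1941
null0076	228	228	180
null0077	551	557	387
null0078	892	872	669
null0079	102	97	50
null0080	569	542	554
null0081	470	437	372
null0082	525	458	331
null0083	306	311	468
null0084	598	564	351
null0085	349	327	397
null0086	92	101	126
null0087	662	631	558
null0088	53	64	45
null0089	158	131	195
null0090	151	135	127
null0091	299	295	365
null0092	75	81	39
null0093	400	416	314
null0094	41	39	71
null0095	83	90	52
null0096	80	96	99
null0097	640	564	1699
null0098	296	266	195
null0099	48	63	86
null0100	65	65	80
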