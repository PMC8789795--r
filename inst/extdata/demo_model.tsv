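#tcsp_shem	version	1
#param	pseudocount	num	1
#param	cv_max	num	0.25
#param	cpm_min	num	15
#param	n_target	int	4
#param	bg_threshold	num	0.20000000000000001
#param	excluded_origins	chr	haematopoietic,lymphoid,leukemia,lymphoma,myeloma
#audit_cols	gene	subtype	rank_value	cv	max_cpm	background_score	status	reason
#audit	mkN02	N	3.0359848618029219	0.075486981103273829	32819.437090138897	0	kept	
#audit	mkN01	N	2.9687068261325367	0.059957856992814688	72323.782999022253	0	kept	
#audit	mkN03	N	2.9053859538739264	0.087507409398804761	90891.089108910892	0	kept	
#audit	mkN04	N	2.9051677063917456	0.11397206624417852	25075.078022258425	0	kept	
#audit	mkA03	A	3.1952109129671578	0.09842182823694573	75195.233878109648	0	kept	
#audit	mkA01	A	3.0683703305463763	0.1475939185687116	77891.692690813055	0	kept	
#audit	mkA04	A	2.9903104376990677	0.10315813599720718	36898.099127716428	0	kept	
#audit	mkA02	A	2.8720967843773169	0.17690072473653726	25404.922329219677	0	kept	
#audit	mkEX01	EX	3.1677278457004441	0.11898318890814154	71854.454995952692	0	kept	
#audit	mkEX04	EX	3.1456905050803501	0.062685275545190849	30860.540084557681	0	kept	
#audit	mkEX03	EX	3.1203541376545951	0.10222500230435011	30363.519640492716	0	kept	
#audit	mkEX02	EX	3.1169645583742258	0.045236833065125791	25097.299683023713	0	kept	
#audit	mkEM04	EM	3.0569846747830347	0.08653940816761814	74444.400661990701	0	kept	
#audit	mkEM01	EM	2.9088710560864546	0.10919081624721179	102384.03431154731	0	kept	
#audit	mkEM03	EM	2.8945482632051474	0.067011072461190591	52336.701377484977	0	kept	
#audit	mkEM02	EM	2.8645602072159719	0.10281998007455886	71918.987341772154	0	kept	
#audit	mkCM02	CM	3.0412890860042778	0.10701137651047865	83456.58561596561	0	kept	
#audit	mkCM01	CM	2.9968352467779287	0.12218238097467454	78496.913762842887	0	kept	
#audit	mkCM04	CM	2.9592406077128914	0.060037975410906691	23256.997455470741	0	kept	
#audit	mkCM03	CM	2.9495924916819112	0.13593916582229804	39959.287531806614	0	kept	
gene	N	A	EX	EM	CM
mkN02	29305.499827354168	3844.1680887814287	3562.4931813195058	3515.2884214663763	3413.7576885015646
mkN01	67443.049523974085	8566.6987294377614	9044.3153863146727	8161.8028289541917	8556.4181008332725
mkN03	81062.267112273737	10238.637855275678	11815.234599130697	9866.9508425297463	10992.021019607088
mkN04	21629.849518101935	3063.1216286686226	3003.43491606831	2698.9038260086945	2789.0064499389396
mkA03	7234.2299967844137	68431.006316207538	7969.492433771391	7076.2092127043561	7759.3595898512949
mkA01	8328.645156879973	69057.882635495451	8866.6825048924384	7194.813872860449	8432.157447556956
mkA04	4190.9002385623899	34634.917019859437	4913.6719360711686	4015.8225602063667	4260.0990681185358
mkA02	2776.4297930740399	21227.883542772546	3176.123841257016	2683.3652598654417	3028.151302245677
mkEX01	7072.037084969741	7094.8897152862346	61807.67886653082	6478.7538291008168	6803.3758536771284
mkEX04	3413.4273088569867	3130.0726253374637	28971.40978211613	3253.6447128622685	3071.743741812877
mkEX03	3230.8815302919256	2585.7316375540445	25470.966706583895	2848.3278338135383	2596.3500018221762
mkEX02	2903.4787070016887	2693.7812743827458	24239.006594909559	2680.5570684845088	2785.2787492046
mkEM04	7928.9727028981124	7550.220297490222	8243.6955358254872	65542.761919542507	7316.2336828379694
mkEM01	11391.279552399134	12127.320966992274	12529.157418444769	89551.146277478838	11923.661260541756
mkEM03	6559.0419540599942	6419.7643948197237	6799.5984861896968	48429.025611525954	5902.370647382555
mkEM02	8627.8289254570973	8487.9262086683466	9380.3694031183277	64367.026806287555	8656.8059833799725
mkCM02	8675.4928634110565	8634.793622919211	9898.0357506756154	9042.2153436701738	74811.41756828448
mkCM01	8393.7330070742264	8358.9920649604774	9820.0091461310021	8346.0972265933524	69990.524832135095
mkCM04	2865.6496378338707	2878.1814460037745	2865.1419504872674	2575.9404977223844	21793.492405492172
mkCM03	4805.1079431909793	4461.5726642590434	4566.8761365771124	4296.7578916934453	35371.29983820425
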