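specimen_id	family	species	amplified_its2	amplified_its	its1_bp	r58s_bp	its2_bp	accession
CE18252	Branchiobdellidae	Xironogiton victoriensis	+	+	>1097	153	>810	KY982581
CE14346	Capilloventridae	Capilloventer australis	+	-	-	>92	747	KY982554
CE13745	Enchytraeidae	Achaeta aberrans	+	+	>439	153	330	KY982545
CE11317	Enchytraeidae	Chamaedrilus sphagnetorum	+	-	-	>70	248	KY982555
CE19554	Enchytraeidae	Fridericia magna	+	+	>436	153	287	KY982559
CE19299	Enchytraeidae	Lumbricillus lineatus	+	+	>464	153	289	KY982569
CE5731	Haplotaxidae	Haplotaxis gordioides	+	+	>472	153	302	KY982561
CE18378	Hirudinidae	Haemopis sanguisuga	+	+	>322	153	381	KY982560
CE12000	Lumbricidae	Allolobophora caliginosa	+	+	>503	153	416	KY982547
CE16075	Lumbricidae	Aporrectodea caliginosa	+	+	>389	153	416	KY982549
CE10969	Lumbriculidae	Dorydrilus michaelseni	-	-	-	-	-	-
CE14379	Lumbriculidae	Kincaidiana hexatheca	+	+	>546	153	313	KY982565
CE19888	Lumbriculidae	Lumbriculus variegatus	+	+	>638	153	312	KY982570
CE17795	Lumbriculidae	Stylodrilus heringianus	+	-	-	>107	321	KY982578
CE2048	Megascolecidae	Dichogaster bolaui	+	+/-	>93	153	338	KY982556
CE713_1	Naididae	Branchiura sowerbyi	-	-	-	-	-	-
CE10030	Naididae	Adelodrilus pusillus	+	+	>490	153	385	KY982546
CE37	Naididae	Aktedrilus arcticus	+	+	>459	153	258	KY637025
CE1790	Naididae	Aulodrilus acutus	+	+	>426	153	377	KY637027
CE14362	Naididae	Aulodrilus japonicus	+	+	>515	153	389	KY982550
CE281	Naididae	Aulodrilus pluriseta	+	-	-	>64	288	KY637028
CE196_2	Naididae	Baltidrilus costatus	+	+	>715	153	481	KY637029
CE17439	Naididae	Bathydrilus formosus	+	+	>591	153	357	KY982551
CE17759	Naididae	Bothrioneurum vejdovskyanum	+	+	351	153	251	KY982552
CE2213	Naididae	Branchiodrilus hortensis	-	-	-	-	-	-
CE12487	Naididae	Branchiura sp	+	+/-	>118	153	642	KY982553
CE112	Naididae	Clitellio arenarius	+	+	380	153	302	KY637031
CE138	Naididae	Doliodrilus tener	+	+	>669	153	282	KY637032
CE14133	Naididae	Doliodrilus tener	+	+	>573	153	256	KY982557
CE754	Naididae	Epirodrilus pygmaeus	+/-	-	-	>70	>84	KY982558
CE236	Naididae	Heronidrilus fastigatus	+	+	444	153	285	KY637033
CE18212	Naididae	Heronidrilus gravidus	+	+	>472	153	247	KY982562
CE17490	Naididae	Heterodrilus ersei	+	+	>377	153	296	KY982563
CE18015	Naididae	Inanidrilus leukodermatus	+	+	416	153	258	KY982564
CE131	Naididae	Limnodriloides anxius	+	+	>880	153	353	KY637034
CE16954	Naididae	Limnodriloides australis	+	+	>876	153	312	KY982566
CE2730	Naididae	Limnodrilus cf. cervix	+	+	>480	153	408	KY982567
CE2128	Naididae	Limnodrilus claparedianus/cervix	+	+	378	153	346	KY369387
CE1785	Naididae	Limnodrilus grandisetosus	+	+	471	153	515	KY637016
CE1786	Naididae	Limnodrilus grandisetosus	+	-	-	>107	359	KY637017
CE1784	Naididae	Limnodrilus hoffmeisteri IX	+	+	341	153	341	KY369406
CE22814	Naididae	Limnodrilus hoffmeisteri II	+	-	-	>70	342	KY652931
CE2740	Naididae	Limnodrilus hoffmeisteri VIII	+	+	349	153	328	KY369440
CE1991	Naididae	Limnodrilus hoffmeisteri X	+	+	338	153	340	KY369446
CE10781	Naididae	Limnodrilus rubripenis	+	+	547	153	422	KY637018
CE10853	Naididae	Limnodrilus rubripenis	+	+	550	153	432	KY637020
CE10482	Naididae	Limnodrilus sulphurensis	+	+	>589	153	383	KY637022
CE1839	Naididae	Limnodrilus udekemianus	+	+	>524	153	392	KY982568
CE211	Naididae	Lophochaeta ignota	+	+/-	>188	153	439	KY637036
CE20081	Naididae	Monopylephorus irroratus	+	+	>370	153	330	KY982571
CE50	Naididae	Monopylephorus rubroniveus	+	+	>435	153	370	KY637037
CE19318	Naididae	Nais elinguis	+	+	>421	153	292	KY982572
CE16885	Naididae	Olavius albidus	+	+	>400	153	274	KY982573
CE17410	Naididae	Potamothrix bavaricus	+	+	>479	153	383	KY982574
CE283	Naididae	Potamothrix moldaviensis	+	+	>466	153	396	KY637042
CE2883	Naididae	Psammoryctides albicola	+	+	>487	153	518	KY637043
CE289	Naididae	Psammoryctides barbatus	+	+	391	153	373	KY637044
CE623	Naididae	Rhyacodrilus coccineus	+	+	340	153	308	KF267996
CE17550	Naididae	Smithsonidrilus hummelincki	+	+/-	>69	153	697	KY982576
CE1984	Naididae	Spirosperma ferox	+	-	-	>69	>306	KY982577
CE18140	Naididae	Thalassodrilides bruneti	+	+	>514	153	281	KY982579
CE2038	Naididae	Trieminentia corderoi	+/-	-	-	>63	>161	KY982580
CE2044	Naididae	Tubifex blanchardi	+	+	>604	153	446	KY637046
CE272	Naididae	Tubifex newaensis	+	+	>490	153	336	KY637047
CE212	Naididae	Tubifex smirnowi	+	+	447	153	321	KY637048
CE276	Naididae	Tubifex tubifex	+	+	>515	153	393	KY637049
CE186	Naididae	Tubificoides benedii	+	+	>464	153	332	KY637050
CE3600	Naididae	Varichaetadrilus cf. angustipenis	-	-	-	-	-	-
CE3621	Naididae	Varichaetadrilus sp	+	+/-	-	>105	494	KY637051
CE14357	Phreodrilidae	Antarctodrilus proboscidea	+	-	-	>85	747	KY982548
CE14476	Randiellidae	Randiella sp	+	+	>548	153	319	KY982575
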