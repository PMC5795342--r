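sample_id	species	clean_data_gb	total_reads	q30_pct	n_contigs	n50_bp	mean_bp	genes_matrix1	genes_matrix2
RS1	Pronephrium simplex	4.7	38045864	91.24	151319	887	581.07	2168	1254
RS10	Antrophyum callifolium	4.0	32745384	91.76	64107	1819	998.73	2226	1305
RS101	Oleandra musifolia	4.5	36487068	91.45	37075	1493	919.3	2093	1248
RS103	Woodsia polystichoides	3.9	31465870	90.91	47812	1348	811.3	2287	1310
RS107	Equisetum diffusum	4.4	35693238	90.21	88932	1154	655.64	1811	1254
RS108	Oreogrammitis dorsipila	4.6	37037324	90.57	266540	591	485.1	2141	1273
RS11	Vandenboschia striata	4.8	38639790	90.3	261724	460	422.76	1959	1276
RS111	Pleurosoriopsis makinoi	4.8	38983796	90.13	98187	1145	632.29	2182	1277
RS112	Azolla pinnata subsp. asiatica	4.4	35735206	90.57	78295	1348	777.92	1418	839
RS114	Taenitis blechnoides	4.1	32898682	90.98	70495	1262	711.3	2186	1278
RS115	Gymnogrammitis dareiformis	3.9	31630988	89.81	119483	569	449.38	1996	1220
RS116	Schizaea dichotoma	4.5	36668734	89.6	67422	1350	826.92	2035	1285
RS119	Botrychium japonicum	4.8	38603000	90.28	85236	1477	846.97	1866	1283
RS122	Goniophlebium niponicum	4.8	38786214	90.82	54152	1663	951.92	2279	1300
RS123	Arthropteris palisotii	4.4	35646740	91	50700	1454	891.67	2286	1311
RS124	Matteuccia struthiopteris	4.2	34080998	90.44	57514	1345	776.52	2290	1313
RS127	Salvinia natans	4.2	33780056	91.17	79393	1379	767.14	1905	1173
RS128	Woodwardia prolifera	5.1	40967322	91.63	69931	1557	859.72	2328	1328
RS14	Diplazium viridescens	4.0	32320416	90.46	88236	1434	780.87	2269	1310
RS16	Bolbitis appendiculata	4.7	37503336	91.66	201426	802	556.39	2226	1288
RS17	Dryopteris pseudocaenopteris	4.1	33136196	91.23	102751	723	514.92	2236	1298
RS18	Dicranopteris pedata	4.2	33942120	92.04	74011	1193	684.09	2031	1304
RS19	Haplopteris amboinensis	4.2	42772168	94.17	47603	1713	1041.8	2249	1307
RS21	Psilotum nudum	8.5	85199034	93.6	66212	1739	927.19	1741	1223
RS24	Cyclopeltis crenata	4.6	37158058	91.5	29668	600	491.82	2146	1279
RS25	Asplenium formosae	4.6	46629754	93.5	73318	1722	989.84	2273	1312
RS27	Lomariopsis spectabilis	4.1	33233594	91.77	98030	1466	750.42	2225	1304
RS28	Cheiropleuria bicuspis	5.1	41617294	91.35	99411	1435	832.82	2022	1295
RS31	Plagiogyria japonica	5.7	46472760	91.92	89532	1258	733.9	2036	1222
RS34	Alsophila podophylla	4.9	48768608	93.43	66254	1580	904.62	2195	1289
RS35	Histiopteris incisa	4.3	43115390	93.81	61231	1749	985.03	2319	1316
RS36	Pteris vittata	4.1	41212858	94.37	76666	1868	1021.13	2296	1312
RS37	Cibotium barometz	4.1	33263550	91.92	85555	1612	891.87	1790	1099
RS38	Osmunda japonica	4.1	33485274	92.05	58612	1730	901.28	1732	1159
RS39	Loxogramme chinensis	3.9	31392952	92.16	84796	1065	651.88	2240	1305
RS4	Microlepia hookeriana	4.0	40561422	94.49	95951	1610	874.06	2262	1301
RS41	Pteridium aquilinum	4.6	46157134	93.51	55615	1742	960.37	2321	1316
RS42	Hypolepis punctata	4.4	43828154	93.56	59717	1371	833.68	2277	1308
RS43	Dicksonia antarctica	3.9	31210608	91.69	56494	1533	902.96	2045	1213
RS45	Rhachidosorus mesosorus	4.4	35348994	91.98	80069	1541	835.92	2300	1315
RS46	Drynaria bonii	4.5	36017548	92.02	68132	1077	643.93	2176	1279
RS47	Platycerium bifurcatum	4.1	33209740	91.62	40456	1097	694.56	2148	1283
RS48	Angiopteris fokiensis	4.4	35120302	91.12	57637	1629	932.57	1917	1306
RS5	Diplaziopsis brunoniana	4.3	34698846	91.35	70184	822	541.31	2040	1234
RS50	Dennstaedtia pilosella	4.5	45618446	93.63	84813	1582	831.56	2308	1313
RS51	Monachosorum henryi	4.1	41658504	93.42	87832	1465	803.17	2255	1288
RS52	Acystopteris japonica	5.5	44662146	91.15	57118	1507	873.59	1222	677
RS53	Monachosorum maximowiczii	4.8	48497004	93.58	101448	1817	899.54	2257	1294
RS54	Dennstaedtia scabra	5.1	51360716	93.47	92158	1565	845.44	1818	1056
RS56	Arachniodes nigrospinosa	5.1	50929362	94.47	57168	1623	916.1	2332	1319
RS69	Cheilanthes chusana	5.2	51851066	94.18	49449	1727	1012.63	2317	1324
RS7	Elaphoglossum mcclurei	4.1	32800248	92.31	57330	1398	846.79	2267	1299
RS70	Lomagramma matthewii	4.4	35218876	91.21	65170	1748	947.18	2258	1307
RS71	Osmolindsaea odorata	4.6	46808646	94.13	113778	1521	845.96	2257	1312
RS72	Aleuritopteris chrysophylla	4.8	47955674	94.18	61637	1669	929.63	2307	1322
RS77	Marsilea quadrifolia	4.3	34724432	91.76	65227	1607	930.31	2188	1299
RS8	Humata repens	4.5	36606746	91.17	68932	1267	690.35	2264	1315
RS81	Tectaria subpedata	4.2	42539482	94.43	57384	1326	797.83	2128	1242
RS84	Ophioglossum vulgatum	4.4	35637330	91.77	71821	1226	741.62	1631	1179
RS85	Nephrolepis cordifolia	5.0	40063236	90.81	55207	1530	842.63	2302	1319
RS86	Microlepia platyphylla	4.6	46324294	94	74956	1763	945.87	2267	1295
RS88	Lygodium flexuosum	4.2	34098316	91.44	66751	1514	867.82	2064	1296
RS89	Hypodematium crenatum	4.1	32711798	91.58	52813	1416	852.57	2298	1319
RS90	Acrostichum aureum	5.4	43422574	90.69	46189	1729	1043.2	2303	1319
RS91	Adiantum caudatum	5.1	51062204	94.23	51145	1575	950.49	2323	1327
RS92	Parahemionitis cordata	4.1	33309450	91.72	47508	1456	894.42	2306	1317
RS93	Microlepia speluncae	4.4	44124842	94.55	94980	1720	917.59	2292	1308
RS97	Stenochlaena palustris	4.7	37887642	91.81	58416	1655	945.83	2300	1316
RS98	Ceratopteris thalictroides	3.9	31741082	91.4	74728	1610	912.26	2231	1296
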