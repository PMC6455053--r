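recombination	isolates	locus1_name	locus1_length	locus1_start	locus1_end	locus2_name	locus2_length	locus2_start	locus2_end	homology	chimera_length	locus_class
ΔSe(YAR050W-YARend)::Se(YALend-YAL063C)	IMS0614	SeFLO1	5517	711	734	SeFLO9	4752	712	735	79.23	4752	ORF
ΔSe::Sc(YBR275C-YBRend)	IMS0561	ScRIF1	5751	562	572	SeRIF1	5751	569	579	77.49	5745	ORF
ΔSc::Se(YDR051C-YDRend)	IMS0567	SeDET1	1005	426	434	ScDET1	1005	427	435	84.36	1005	ORF
ΔSc::Se(YGR218C-YGRend)	IMS0558	ScCRM1	3251	2626	2636	SeCRM1	3251	2627	2637	85.84	3251	ORF
ΔSc::Se(YGR271W-YGRend)	IMS0567	ScSLH1	5904	1335	1349	SeSLH1	5901	1336	1350	82.41	5901	ORF
ΔSc(YGR279C-YGRend)::Se(YMR305C-YMRend)	IMS0563	SeSCW10	1146	892	899	ScSCW4	1161	908	915	<70	1146	ORF
ΔSc::Se(YGR282C-YGRend)	IMS0554	SeBGL2	942	115	125	ScBGL2	942	116	126	87.75	942	ORF
ΔSc::Se(YHLend-YHL023C)	IMS0552	SeNPR3	3444	1551	1571	ScNPR3	3441	1561	1581	78.80	3432	ORF
ΔSe::Sc(YKLend-YKL057C);ΔSc::Se(YKL057C-YKRend)	IMS0548	SeNUP120	3114	1867	1868	ScNUP120	3114	1868	1869	80.14	3114	ORF
ΔSc::Se(YLR154C-YLRend)	IMS0544	rDNA	NA	NA	NA	rDNA	NA	NA	NA	NA	NA	rDNA
ΔSe::Sc(YLR154C-YLRend)	IMS0599	rDNA	NA	NA	NA	rDNA	NA	NA	NA	NA	NA	rDNA
ΔSc::Se(YLR305C-YLRend)	IMS0604	SeSTT4	5703	5013	5018	ScSTT4	5703	5014	5019	81.64	5703	ORF
ΔSc::Se(YNL061C-YNL055C)	IMS0562	ScNOP2	1857	1386	1391	SeNOP2	1860	1390	1395	87.11	1857	ORF
ΔSc::Se(YNL061C-YNL055C)	IMS0562	ScPOR1	852	399	401	SePOR1	852	400	402	85.82	852	ORF
ΔSe::Sc(YNLend-YNL123W)	IMS0603	ScNMA111	2994	303	314	SeNMA111	2994	304	315	83.61	2994	ORF
ΔSc::Se(YOL013C-YOL006C)	IMS0603	SeTOP1	2304	2010	2021	ScTOP1	2311	2017	2028	82.64	2304	ORF
ΔSe::Sc(YOLend-YOL013C)	IMS0603	SeHRD1	1644	312	329	ScHRD1	1656	313	330	82.82	1656	ORF
ΔSe::Sc(YOLend-YOL057W)	IMS0597	ScYOL057W	3015	99	116	SeYOL057W	2133	100	117	<70	2133	ORF
ΔSe::Sc(YOLend-YOL072W)	IMS0595	ScTHP1	1368	726	731	SeTHP1	1374	733	738	79.07	1368	ORF
ΔSe::Sc(YOLend-YOL075W)	IMS0600	SeYOL075C	3903	2409	2414	ScYOL075C	3885	2392	2397	81.85	3903	ORF
ΔSe::Sc(YOR063W-YORend)	IMS0560	ScRPL3	1164	1023	1063	SeRPL3	1164	1024	1064	94.59	1164	ORF
ΔSe::Sc(YOR133W-YORend)	IMS0559,IMS0561,IMS0562	ScEFT1	2529	246	311	SeEFT1	2529	247	312	94.94	2529	ORF
ΔSc(YCLend-YCL067C);ΔSc(YCR039C-YCRend)	IMS0551	ScHMLALPHA2	633	1	633	ScMATALPHA2	633	1	633	100	633	ORF
ΔSc(YDR261C-YDR211W)	IMS0558,IMS0560	TY-transposon	NA	NA	NA	TY-transposon	NA	NA	NA	NA	NA	Ty_transposon
ΔSc(YKL032C-YKL054C)	IMS0543,IMS0544,IMS0545,IMS0546,IMS0547,IMS0599,IMS0601,IMS0602	ScIXR1	1794	944	955	ScDEF1	2217	1281	1292	<70	1881	ORF
ΔSc(YKL032C-YKL054C)	IMS0604,IMS0605,IMS0606,IMS0607,IMS0608	ScIXR1	1794	332	341	ScDEF1	2217	1272	1281	<70	1278	ORF
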