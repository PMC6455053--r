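line_id	condition	cycles	generations	isolate_id	maltotriose	flocculation	respiration	mito_status	aneuploidy	segmental	snps	indels
LG12.1	3x diluted wort, 12C	29	116	IMS0538	+	-	+
LG12.1	3x diluted wort, 12C	29	116	IMS0539	+	-	+
LG12.1	3x diluted wort, 12C	29	116	IMS0540	+	-	+				SeHDA2^A1651T	SeMED2^462+3N
LG12.1	3x diluted wort, 12C	29	116	IMS0541	+	-	-	rho0
LG12.1	3x diluted wort, 12C	29	116	IMS0542	+	-	+				ScIQG1^A2069C	SeKEX1^1875-6N
LG12.1	3x diluted wort, 12C	29	116	IMS0543	+	+	+			ΔSc(YKL032C-YKL054C)
LG12.1	3x diluted wort, 12C	29	116	IMS0544	+	+	+			ΔSc(YKL032C-YKL054C);ΔSc::Se(YLR154C-YLRend)	SeSAC1^G1093C
LG12.1	3x diluted wort, 12C	29	116	IMS0545	+	+	+			ΔSc(YKL032C-YKL054C)		SeNAF1^1404-30N;SeNAF1^1436-30N
LG12.1	3x diluted wort, 12C	29	116	IMS0546	+	+	-	rho-		ΔSc(YKL032C-YKL054C)
LG12.1	3x diluted wort, 12C	29	116	IMS0547	+	+	+			ΔSc(YKL032C-YKL054C)
LG12.1	3x diluted wort, 12C	58	232	IMS0594	+	-	+					SeELA1^230+343N;SeIRA2^1402-1N;ScFLO9*
LG12.1	3x diluted wort, 12C	58	232	IMS0595	+	-	+		2xSe(CHRVIII)	ΔSe::Sc(YOLend-YOL072W)
LG12.1	3x diluted wort, 12C	58	232	IMS0596	+	-	+				SeIRA2^C1376A;ScYER188W^T28A
LG12.1	3x diluted wort, 12C	58	232	IMS0597	+	-	+			ΔSe::Sc(YOLend-YOL057W)	SeNUP1^C1205T;ScPDC2^G372A
LG12.1	3x diluted wort, 12C	58	232	IMS0598	+	-	+				SeSRT1^C359T	SeASG1^2488+3N
LG12.1	3x diluted wort, 12C	58	232	IMS0599	+	+	+			ΔSc(YKL032C-YKL054C);ΔSe::Sc(YLR154C-YLRend)
LG12.1	3x diluted wort, 12C	58	232	IMS0600	+	-	+			ΔSe::Sc(YOLend-YOL075W)	SeMSR1^A853C
LG12.1	3x diluted wort, 12C	58	232	IMS0601	+	+	-	rho-		ΔSc(YKL032C-YKL054C)
LG12.1	3x diluted wort, 12C	58	232	IMS0602	+	+	+			ΔSc(YKL032C-YKL054C)
LG12.1	3x diluted wort, 12C	58	232	IMS0603	+	-	+			ΔSe::Sc(YNLend-YNL123W);ΔSe::Sc(YOLend-YOL013C);ΔSc::Se(YOL013C-YOL006C)
LG12.2	3x diluted wort, 12C	29	116	IMS0548	+	-	+			ΔSe::Sc(YKLend-YKL057C);ΔSc::Se(YKL057C-YKRend)
LG12.2	3x diluted wort, 12C	29	116	IMS0549	+	-	-	rho-
LG12.2	3x diluted wort, 12C	29	116	IMS0550	+	-	-	rho-
LG12.2	3x diluted wort, 12C	29	116	IMS0551	+	-	-	rho-		ΔSc(YCLend-YCL067C);ΔSc(YCR039C-YCRend)
LG12.2	3x diluted wort, 12C	29	116	IMS0552	+	-	-	rho-		ΔSc::Se(YHLend-YHL023C)
LG12.2	3x diluted wort, 12C	57	228	IMS0604	+	-	+			ΔSc(YKL032C-YKL054C);ΔSc::Se(YLR305C-YLRend)	SeBET2^G550A
LG12.2	3x diluted wort, 12C	57	228	IMS0605	+	-	+			ΔSc(YKL032C-YKL054C)
LG12.2	3x diluted wort, 12C	57	228	IMS0606	+	-	-	rho-	ΔSe(CHRVIII)	ΔSc(YKL032C-YKL054C)	ScLRG1^C2277G
LG12.2	3x diluted wort, 12C	57	228	IMS0607	+	-	+			ΔSc(YKL032C-YKL054C)		SeFLO11*
LG12.2	3x diluted wort, 12C	57	228	IMS0608	+	-	-	rho-		ΔSc(YKL032C-YKL054C)
LG30.1	3x diluted wort, 30C	116	464	IMS0553	+	-	+					SeNHX1^1622+3N
LG30.1	3x diluted wort, 30C	116	464	IMS0554	-	-	+			ΔSc::Se(YGR282C-YGRend)		ScCIS3*
LG30.1	3x diluted wort, 30C	116	464	IMS0555	+	-	+				SeBAT1^G1073A;ScMAL23^G422A
LG30.1	3x diluted wort, 30C	116	464	IMS0556	+	-	+		2xSc(CHRVIII)		SeGMC1^G1579A;ScSFL1^T605A
LG30.1	3x diluted wort, 30C	116	464	IMS0557	-	-	+				ScMAL11^G88T;ScMAL11^A98G;ScMDL2^C1451A	ScMAL11^93-1N;SeYNL247W^2062-1N
LG30.1	3x diluted wort, 30C	116	464	IMS0558	-	+	+			ΔSc(YDR261C-YDR211W);ΔSc::Se(YGR218C-YGRend)	ScSFL1^T605A	SeSFL1^96+1N
LG30.1	3x diluted wort, 30C	116	464	IMS0559	+	+	+			ΔSe::Sc(YOR133W-YORend)	ScSFL1^T605A
LG30.1	3x diluted wort, 30C	116	464	IMS0560	+	+	+		2xSe(CHRX)	ΔSc(YDR261C-YDR211W);ΔSe::Sc(YOR063W-YORend)	ScSFL1^T605A
LG30.1	3x diluted wort, 30C	116	464	IMS0561	+	+	+			ΔSe::Sc(YBR275C-YBRend);ΔSe::Sc(YOR133W-YORend)	ScSFL1^T605A
LG30.1	3x diluted wort, 30C	116	464	IMS0562	+	+	+			ΔSc::Se(YNL061C-YNL055C);ΔSe::Sc(YOR133W-YORend)	ScSFL1^T605A
LG30.2	3x diluted wort, 30C	117	468	IMS0563	-	-	+			ΔSc(YGR279C-YGRend)::Se(YMR305C-YMRend)	SeROG3^G191A;SeMSS51^C448T	ScRTP1^874-64N
LG30.2	3x diluted wort, 30C	117	468	IMS0564	+	-	+				SeIZH3^A526G;ScCST6^C807A
LG30.2	3x diluted wort, 30C	117	468	IMS0565	-	-	+		ΔSc::Se(CHRXIV)		ScMAL11^A1G
LG30.2	3x diluted wort, 30C	117	468	IMS0566	+	-	-	rho-			ScERG6^C413T;ScBUL1^G2110A	SeYBR238C^315-36N
LG30.2	3x diluted wort, 30C	117	468	IMS0567	-	-	-	rho-		ΔSc::Se(YDR051C-YDRend);ΔSc::Se(YGR271W-YGRend)		ScULP2^1469+1N
HG12.1	full-strength wort, 12C	13	52	IMS0609	+	-	+
HG12.1	full-strength wort, 12C	13	52	IMS0610	+	-	-	rho-			ScYBR259W^C833A
HG12.1	full-strength wort, 12C	13	52	IMS0611	+	-	-	rho-			ScFMP52^G406C
HG12.1	full-strength wort, 12C	13	52	IMS0612	+	-	+
HG12.1	full-strength wort, 12C	13	52	IMS0613	+	-	+				SeGIC2^C344G	SeGCN2^2274+18N;SeGCN2^2239+18N;SeTRA1^4421-25N
HG12.2	full-strength wort, 12C	16	64	IMS0614	+	-	+			ΔSe(YAR050W-YARend)::Se(YALend-YAL063C)	SeSFL1^C1390T
HG12.2	full-strength wort, 12C	16	64	IMS0615	+	-	+				ScCAC2^A994T
HG12.2	full-strength wort, 12C	16	64	IMS0616	+	-	-	rho-			ScATG1^A434C
HG12.2	full-strength wort, 12C	16	64	IMS0617	+	-	+				SeSFL1^C1390T
HG12.2	full-strength wort, 12C	16	64	IMS0618	+	-	-	rho-			ScALR1^G1645T
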