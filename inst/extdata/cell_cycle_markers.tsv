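phase	marker	compartment
early G1	CCND1:CDK6(P@Thr):CDKN1B	Nucleoplasm
early G1	pRB:E2F1:DP1:SWI:SNF:HDAC1	Nucleoplasm
early G1	SWI:SNF:HDAC1:SUV39H1:pRB:E2F1:DP1	Nucleoplasm
early G1	CCND1:CDK4(P@Thr172):CDKN1B	Nucleoplasm
early G1	pRB:E2F1:DP1:SWI:SNF:HDAC1:SUV39H1:HP1gamma	Nucleoplasm
late G1	pRB(P):E2F1:DP1:SWI:SNF:HDAC1	Nucleoplasm
late G1	pRB(P|P):E2F1:DP1:SWI:SNF	Nucleoplasm
early S	CCNE1:CDK2(P@Thr160)	Nucleoplasm
late S	CCNA2:CDK2(P@Thr160)	Nucleoplasm
G2	CCNB1:CDK1(P@Tyr15)	Cytoplasm
G2	CCNB1:CDK1(P@Tyr15|P@Thr14)	Cytoplasm
G2	CCNB1:CDK1	Cytoplasm
G2	CCNB1:CDK1(P@Thr14)	Cytoplasm
M	CDC25(P)	Nucleoplasm
M	WEE1(P@Ser53)	Nucleoplasm
M	CCNB1:CDK1(P@Thr161)	Nucleoplasm
M	CDC20(P)	Nucleoplasm
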