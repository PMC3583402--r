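#length=16569 circular=1 name=human_mtDNA
gene	tRNA-Phe	577	647	heavy	.
gene	12S	648	1601	heavy	.
gene	tRNA-Val	1602	1670	heavy	.
gene	16S	1671	3229	heavy	.
gene	tRNA-Leu1	3230	3304	heavy	.
gene	ND1	3307	4262	heavy	.
gene	tRNA-Ile	4263	4331	heavy	.
gene	tRNA-Gln	4329	4400	light	.
gene	tRNA-Met	4402	4469	heavy	.
gene	ND2	4470	5511	heavy	.
gene	tRNA-Trp	5512	5579	heavy	.
gene	tRNA-Ala	5587	5655	light	.
gene	tRNA-Asn	5657	5729	light	.
gene	tRNA-Cys	5761	5826	light	.
gene	tRNA-Tyr	5826	5891	light	.
gene	COX1	5904	7445	heavy	.
gene	tRNA-Ser1	7446	7514	light	.
gene	tRNA-Asp	7518	7585	heavy	.
gene	COX2	7586	8269	heavy	.
gene	tRNA-Lys	8295	8364	heavy	.
gene	ATP8	8366	8572	heavy	.
gene	ATP6	8527	9207	heavy	.
gene	COX3	9207	9990	heavy	.
gene	tRNA-Gly	9991	10058	heavy	.
gene	ND3	10059	10404	heavy	.
gene	tRNA-Arg	10405	10469	heavy	.
gene	ND4L	10470	10766	heavy	.
gene	ND4	10760	12137	heavy	.
gene	tRNA-His	12138	12206	heavy	.
gene	tRNA-Ser2	12207	12265	heavy	.
gene	tRNA-Leu2	12266	12336	heavy	.
gene	ND5	12337	14148	heavy	.
gene	ND6	14149	14673	light	.
gene	tRNA-Glu	14674	14742	light	.
gene	CYTB	14747	15887	heavy	.
gene	tRNA-Thr	15888	15953	heavy	.
gene	tRNA-Pro	15956	16023	light	.
promoter	HSP1	546	562	heavy	tss=561
promoter	HSP2	631	647	heavy	tss=646
promoter	LSP	406	422	light	tss=407
factor	mTERF	3230	3257	both	p=0.016400000000000001;q=0.0055999999999999999;lambda=0.64559999999999995
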