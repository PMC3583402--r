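#length=3000 circular=1 name=toy
gene	gH1	201	700	heavy	.
gene	gH2	901	1400	heavy	.
gene	gL1	2301	2800	light	.
gene	gL2	301	600	light	.
promoter	PH	86	102	heavy	tss=101
promoter	PL	2900	2916	light	tss=2901
factor	TERM	801	828	both	p=0.29999999999999999;q=0.050000000000000003;lambda=0.5
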