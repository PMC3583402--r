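#length=17553 circular=1 name=frog_mtDNA
promoter	HSP1	2087	2103	heavy	tss=2102
promoter	HSP2	2034	2050	heavy	tss=2049
promoter	LSP1	2102	2118	light	tss=2103
promoter	LSP2A	2041	2057	light	tss=2042
promoter	LSP2B	2032	2048	light	tss=2033
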