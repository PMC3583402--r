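#length=16313 circular=1 name=rat_mtDNA
promoter	HSP1	16283	16299	heavy	tss=16298
promoter	HSP2	51	67	heavy	tss=66
promoter	LSP	16192	16208	light	tss=16193
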