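gene	u_eu	du_eu	t_eu	dt_eu	u_hypo	du_hypo	t_hypo	dt_hypo
16S	NA	NA	44.48	6.34	NA	NA	87.5	27.52
COX1	100	16	84.41	27.49	86	13	235.12	48.68
ATP6/8	100	19	78.14	21.05	59	9	277.52	31.58
COX3	100	19	78.14	21.05	59	9	277.52	31.58
ND4	100	16	84.41	27.49	86	13	235.12	48.68
ND5	100	25	46	10.41	52	11	60.52	5.92
CYTB	100	27	63.7	7.82	57	7	204.3	28.64
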