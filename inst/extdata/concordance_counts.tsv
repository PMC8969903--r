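marker	comparator	a	b	c	d
IDH1_R132H	IHC	7	0	1	52
ATRX_loss	IHC	3	1	0	56
1p19q_codeletion	FISH	5	0	0	5
CDKN2AB_loss	FISH	5	0	0	13
TERT_promoter	Sanger	33	0	0	12
EGFR_amplification	FISH	4	1	0	34
chr7_imbalance	FISH	19	0	0	14
chr10_loss	FISH	20	0	0	13
TP53_mutation	IHC	15	3	2	39
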