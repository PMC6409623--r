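agent_id	target_gene_id	supported
tamoxifen	ESR1	1
trastuzumab	ERBB2	1
lapatinib	ERBB2	1
alpelisib	PIK3CA	1
olaparib	BRCA2	1
olaparib	RAD51	1
experimental-a	TOX3	0
experimental-b	CASP8	0
experimental-c	LSP1	0
experimental-d	ATM	0
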