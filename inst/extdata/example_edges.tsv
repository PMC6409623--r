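source	target
ESR1	ERBB2
ESR1	PIK3CA
ERBB2	PIK3CA
ERBB2	TP53
PIK3CA	TP53
TP53	BRCA2
BRCA2	RAD51
FGFR2	MAP3K1
MAP3K1	TP53
LSP1	TOX3
TOX3	CASP8
CASP8	TP53
ATM	BRCA2
ATM	TP53
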