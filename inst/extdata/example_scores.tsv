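gene_id	p_value
ESR1	0.00002
ERBB2	0.00015
PIK3CA	0.0008
TP53	0.0041
BRCA2	0.0102
FGFR2	0.0263
MAP3K1	0.0871
LSP1	0.2230
TOX3	0.4190
CASP8	0.6630
RAD51	0.8120
ATM	0.9400
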