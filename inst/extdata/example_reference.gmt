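breast_cancer_reference	curated example reference	ESR1	ERBB2	PIK3CA	TP53	BRCA2	FGFR2
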