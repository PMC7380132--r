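dataset	class	n_total	n_correct
TCGA	Mes	104	95
TCGA	non-Mes	352	314
GSE9891	Mes	72	71
GSE9891	non-Mes	112	94
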