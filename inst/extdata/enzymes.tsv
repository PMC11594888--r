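name	motif	cut_offset
EcoRI	GAATTC	1
BamHI	GGATCC	1
HindIII	AAGCTT	1
TaqI	TCGA	1
MspI	CCGG	1
ScrFI	CCNGG	2
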