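name	recognition	cut_offset	blocked_by	double_stranded_scan
MspI	CCGG	1	5hmC	FALSE
HpaII	CCGG	1	5mC,5hmC	FALSE
FspBI	CTAG	1		FALSE
BfaI	CTAG	1	5hmC	FALSE
TasI	AATT	0		FALSE
AciI	CCGC	1	5mC,5hmC	TRUE
HinP1I	GCGC	1	5mC,5hmC	FALSE
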