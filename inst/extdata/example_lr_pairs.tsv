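ligand	receptor
IL1B	IL1R1
TNF	TNFRSF1A
TNF	TNFRSF1B
IL6	IL6R
CXCL12	CXCR4
CCL2	CCR2
KITLG	KIT
FLT3LG	FLT3
TGFB1	TGFBR1
IFNG	IFNGR1
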