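housekeeping	common human housekeeping genes used as a normalization baseline	ACTB	GAPDH	B2M	RPL13A	RPLP0	RPS18	TBP	PPIA	PGK1	HPRT1	GUSB	TFRC	SDHA	YWHAZ	UBC	EEF1A1
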