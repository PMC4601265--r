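antigen	cdr3_aa
TT	CARDRGYSYGWFDPW
TT	CARGGLLTGYYFDYW
TT	CARSSGWYVWGSYRW
TT	CTRDLRTGGVGWFDPW
influenza	CARGGTGWDFDYW
influenza	CAKHMSMQQVVSAGWERADLW
influenza	CARSGGWYPFDYW
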