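driver_gene	partner_gene	partner_druggable	evidence_id
TP53	CHK1i_target	TRUE	SL1
PIK3CA	PIK3CB	TRUE	SL2
APC	CTNNB1	TRUE	SL3
PTEN	ATR	TRUE	SL4
MSH2	WRN	TRUE	SL5
FBXW7	AURKA	FALSE	SL6
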