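gene	development_level
KIT	Tclin
PIK3CA	Tclin
MAP2K1	Tclin
FGFR2	Tclin
CTNNB1	Tchem
MYC	Tbio
TP53	Tchem
FBXW7	Tbio
PTEN	Tchem
APC	Tbio
MSH2	Tbio
TRAF3	Tdark
CHEK2	Tchem
NF1	Tbio
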