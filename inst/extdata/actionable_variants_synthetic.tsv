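gene	protein_change	oncogenicity	level
PIK3CA	H1047R	oncogenic	1
PIK3CA	E545K	oncogenic	1
KIT	V560D	oncogenic	2
MAP2K1	Q57E	likely_oncogenic	3
FGFR2	S252W	oncogenic	2
FBXW7	R465H	likely_oncogenic	4
PTEN	R130Q	likely_oncogenic	3
NF1	R440*	likely_oncogenic	4
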