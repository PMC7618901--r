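gene	protein_change
CHEK2	Y182*
BRIP1	R798*
BRCA1	Q1756*
BRCA2	K3326*
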