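gene
APC
ARID1A
ARID2
ATM
AXIN1
BRAF
CDKN2A
CTNNB1
EGFR
ELF3
EPHA2
ERBB2
ERBB3
FBXW7
GNAS
IDH1
KMT2C
KMT2D
KRAS
NF1
NRAS
PIK3CA
PTEN
RB1
RNF43
SMAD4
SMARCA4
STK11
TERT
TP53
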