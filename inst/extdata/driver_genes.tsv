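# Recurrent lung and pan-cancer driver genes (compact default list)
TP53
KRAS
EGFR
FAT1
PTEN
RB1
CDKN2A
MYC
CCND3
FGFR1
TP63
SETD2
ARID1A
NOTCH2
SMARCA4
STK11
KEAP1
NF1
BRAF
PIK3CA
TSC1
WT1
ERBB3
RHEB
SOS1
SOS2
EZH2
JAK2
ERBB4
ATM
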