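# DNA-repair genes implicated in repair of tobacco-induced damage
ERCC1
ERCC5
ERCC8
LIG4
MUTYH
NEIL1
NEIL3
POLB
RECQL4
REV1
REV3L
TDG
MBD4
RPA1
FANCA
FANCL
RAD50
RAD51B
CHEK1
ATM
ATR
BRCA2
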