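# Demonstration glioma gene panel (60 genes).
# One symbol per line; '#' starts a comment.
TP53
PTEN
EGFR
KMT2D
APC
RB1
CREBBP
SMARCA4
ARID1A
NF1
NOTCH1
PTPN11
BRCA2
RUNX1
STK11
BAP1
VHL
DNMT3A
HNF1A
BTK
POLE
IDH1
IDH2
ATRX
TERT
CDKN2A
CDKN2B
CDK4
CDK6
MDM2
MDM4
PIK3CA
PIK3R1
PDGFRA
MET
FGFR1
FGFR3
H3F3A
BRAF
CIC
FUBP1
NF2
TSC1
TSC2
MSH2
MSH6
MLH1
PMS2
POLD1
SETD2
DAXX
EZH2
KDM6A
SMARCB1
MYC
MYCN
GLI1
SOX2
OLIG2
SUFU
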