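gene	gene_role	ontologies
TP53	tumor_suppressor	missense,frameshift,splice_variant
PTEN	tumor_suppressor	missense
EGFR	oncogene	missense
KMT2D	tumor_suppressor	frameshift,missense
APC	tumor_suppressor	frameshift
RB1	tumor_suppressor	splice_variant
CREBBP	tumor_suppressor	missense
SMARCA4	tumor_suppressor	missense,frameshift
ARID1A	tumor_suppressor	frameshift
NF1	tumor_suppressor	missense,stop_gained
NOTCH1	oncogene	splice_variant
PTPN11	oncogene	missense
BRCA2	tumor_suppressor	frameshift
RUNX1	oncogene	frameshift
STK11	tumor_suppressor	missense
BAP1	tumor_suppressor	missense
VHL	tumor_suppressor	missense
DNMT3A	oncogene	missense
HNF1A	tumor_suppressor	missense
BTK	oncogene	missense
POLE	tumor_suppressor	missense
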