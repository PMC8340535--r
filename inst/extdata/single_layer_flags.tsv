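GENE	RNA_TOP5	PROT_TOP5	PHOS_TOP5
PTEN	0	0	0
STAT3	0	0	0
NFKB1	0	0	0
TNF	0	0	0
AKT1	0	0	0
IGF1R	0	0	0
HIF1A	0	0	0
CAMK2A	0	0	0
ZEB2	0	0	0
GSK3B	1	0	0
ARG1	0	0	0
FBXW7	0	0	0
RUNX1	0	0	0
SIRT1	0	0	0
ZFPM2	0	0	0
AKT2	0	0	0
VEGFA	1	0	0
EGFR	0	0	0
YAP1	0	0	0
ROCK1	0	0	0
MXI1	0	0	0
HDAC4	0	0	0
AKT3	1	0	0
DNMT1	0	0	0
MYC	0	0	0
GSTM1	0	0	0
CCND1	1	0	0
CLIC5	0	0	0
PRKAA1	0	0	0
FLT1	0	0	0
GRB2	0	0	0
ATXN1	0	0	0
FOXO3	0	0	0
KIT	1	0	0
TBX3	0	0	0
UCP2	0	0	0
TSC1	0	0	0
SMAD4	0	0	0
TIMP3	0	0	0
BACE1	0	0	0
RUNX2	1	0	0
YWHAZ	1	0	0
IRS1	0	0	0
KLF4	0	0	0
EZH2	1	0	0
HELLS	0	0	0
BCL2L11	0	0	0
AKT	1	0	0
VCAN	0	0	0
NF1	0	0	0
SRM	0	0	0
AMD1	0	0	0
SEMA4B	0	0	0
ZEB1	0	0	0
MEF2C	1	0	0
CTGF	0	0	0
KRAS	0	0	0
CREB1	0	0	0
RIOK3	0	0	0
EGR1	0	0	0
MECP2	0	0	0
ENPP6	1	0	0
INPP5D	0	0	0
ELK1	0	0	0
PAFAH1B1	0	0	0
MTOR	1	0	0
NR1I3	0	0	0
CAB39	0	0	0
MEOX2	0	0	0
SMAD5	0	0	0
NRAS	0	0	0
YY1	0	0	0
RAF1	0	0	0
CAV2	0	0	0
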