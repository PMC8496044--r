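# Synthetic stand-in immune-specific gene list (canonical lineage and
# effector genes); user-replaceable with any literature-derived list.
PTPRC
CD2
CD3G
CD247
CXCL9
CXCL10
CXCL11
CCL5
IFNG
TNF
IL2RB
IL15
IL12B
TBX21
STAT1
IDO1
GZMB
GZMH
KLRB1
TIGIT
PDCD1
CD274
PDCD1LG2
CTLA4
HAVCR2
BTLA
CD27
TNFRSF9
B2M
HLA-A
HLA-B
HLA-DRA
HLA-DRB1
TAP1
TAP2
PSMB9
PSMB8
C1QA
C1QB
C3
FCGR1A
CD8A
CD8B
GZMK
GZMA
PRF1
KLRG1
EOMES
LAG3
CD3D
CCL4
CD4
IL7R
CD3E
CD28
CCR7
TCF7
LTB
CD40LG
ICOS
SELL
CD19
MS4A1
CD79A
CD79B
BLNK
IGHM
TCL1A
BANK1
CR2
FCRL2
NKG7
KLRD1
KLRF1
NCR1
GNLY
FGFBP2
XCL1
XCL2
KIR2DL3
CD14
LYZ
FCN1
S100A8
S100A9
CSF1R
ITGAM
CD68
MNDA
FCGR3A
FCGR3B
CSF3R
CXCR2
FPR1
MME
CEACAM8
ELANE
MPO
S100A12
SLC25A37
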