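INTERFERON_GAMMA_RESPONSE	synthetic curation: IFN-gamma response module	IFNG	STAT1	CXCL9	CXCL10	CXCL11	IDO1	TAP1	TAP2	PSMB8	PSMB9	HLA-A	HLA-B	B2M
INFLAMMATORY_RESPONSE	synthetic curation: inflammatory mediators	TNF	IL12B	CCL5	CCL4	CXCL9	CXCL10	C3	C1QA	C1QB	FPR1	S100A8	S100A9	S100A12
CYTOTOXIC_LYMPHOCYTE	synthetic curation: cytotoxic effector module	GZMA	GZMB	GZMH	GZMK	PRF1	GNLY	NKG7	KLRD1	KLRF1	EOMES
ANTIGEN_PRESENTATION	synthetic curation: MHC presentation machinery	HLA-A	HLA-B	HLA-DRA	HLA-DRB1	B2M	TAP1	TAP2	PSMB8	PSMB9
T_CELL_COSTIMULATION	synthetic curation: costimulation and checkpoints	CD28	ICOS	CD27	CD40LG	TNFRSF9	CTLA4	PDCD1	TIGIT	BTLA	LAG3	HAVCR2	CD274
B_CELL_RECEPTOR_SIGNALING	synthetic curation: BCR signalling module	CD19	CD79A	CD79B	BLNK	MS4A1	IGHM	BANK1	CR2	FCRL2	TCL1A
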