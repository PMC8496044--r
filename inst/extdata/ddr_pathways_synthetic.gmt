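MISMATCH_REPAIR	synthetic curation: MMR recognition and excision	MSH2	MSH3	MSH6	MLH1	MLH3	PMS1	PMS2	EXO1	POLD1	POLD2	POLD3	POLD4	LIG1	RFC1	RFC2	RFC3	RFC4	RFC5	PCNA
BASE_EXCISION_REPAIR	synthetic curation: glycosylases and short-patch BER	UNG	SMUG1	MBD4	TDG	OGG1	MUTYH	NTHL1	MPG	NEIL1	NEIL2	NEIL3	APEX1	APEX2	POLB	LIG3	XRCC1	PARP1	PARP2	FEN1
NUCLEOTIDE_EXCISION_REPAIR	synthetic curation: NER core incision machinery	XPA	XPC	RAD23A	RAD23B	CETN2	DDB1	DDB2	ERCC1	ERCC2	ERCC3	ERCC4	ERCC5	ERCC6	ERCC8	GTF2H1	GTF2H2	GTF2H3	GTF2H4	GTF2H5	CDK7	CCNH	MNAT1
HOMOLOGOUS_RECOMBINATION	synthetic curation: HR resection and resolution arm	MRE11	RAD50	NBN	BRCA1	BARD1	RBBP8	BLM	DNA2	RPA1	RPA2	RPA3	TOP3A	RMI1	RMI2	EME1	MUS81	GEN1	SLX1A	SLX4	WRN
NON_HOMOLOGOUS_END_JOINING	synthetic curation: classical NHEJ	XRCC6	XRCC5	PRKDC	LIG4	XRCC4	NHEJ1	DCLRE1C	POLL	POLM	TP53BP1	PAXX	APLF	PNKP
HOMOLOGOUS_DNA_PAIRING_AND_STRAND_EXCHANGE	synthetic curation: RAD51-mediated pairing and strand exchange	RAD51	RAD51B	RAD51C	RAD51D	XRCC2	XRCC3	RAD54L	RAD54B	RAD51AP1	DMC1	SWI5	SFR1	SWSAP1	ZSWIM7	PALB2	BRCA2	SEM1	HELQ	MND1	PSMC3IP
DSB_END_RESECTION	synthetic curation: 5'-3' end resection	MRE11	RAD50	NBN	RBBP8	EXO1	BLM	DNA2	WRN	RPA1	RPA2	RPA3
FANCONI_ANEMIA_PATHWAY	synthetic curation: FA core and ID2 complexes	FANCA	FANCB	FANCC	FANCD2	FANCE	FANCF	FANCG	FANCI	FANCL	FANCM	UBE2T	FAAP100	FAAP24	BRIP1	PALB2
DNA_DAMAGE_CHECKPOINT_SIGNALING	synthetic curation: ATM/ATR checkpoint signalling	ATM	ATR	ATRIP	CHEK1	CHEK2	TP53	MDC1	H2AX	TOPBP1	CLSPN	RAD9A	RAD1	HUS1	RAD17	TIMELESS	TIPIN
TRANSLESION_SYNTHESIS	synthetic curation: TLS polymerase switch	POLH	POLI	POLK	REV1	REV3L	MAD2L2	POLN	RAD18	UBE2A	UBE2B	PCNA	SPRTN
DIRECT_REVERSAL_REPAIR	synthetic curation: alkylation reversal	MGMT	ALKBH2	ALKBH3	ASCC1	ASCC2	ASCC3
INTERSTRAND_CROSSLINK_REPAIR	synthetic curation: ICL unhooking and resolution	DCLRE1A	DCLRE1B	FAN1	SLX4	MUS81	EME1	UHRF1	ERCC1	ERCC4
SINGLE_STRAND_BREAK_REPAIR	synthetic curation: SSB detection and ligation	XRCC1	PARP1	PNKP	APTX	TDP1	LIG3	POLB	FEN1
REPLICATION_FORK_PROTECTION	synthetic curation: fork remodelling and protection	ATR	ATRIP	CLSPN	TIMELESS	TIPIN	WRNIP1	SMARCAL1	ZRANB3	HLTF	RECQL5
P53_DAMAGE_RESPONSE	synthetic curation: p53 axis	TP53	MDM2	MDM4	CDKN1A	TP53BP1	USP7	ATM	CHEK2	PPM1D
CELL_CYCLE_CHECKPOINT_ARREST	synthetic curation: damage-induced arrest	CDKN1A	CDC25A	CDC25C	WEE1	CDK1	CCNB1	CHEK1	CHEK2	PLK1	YWHAQ
DNA_DAMAGE_INDUCED_APOPTOSIS	synthetic curation: damage-triggered apoptosis	TP53	BAX	BBC3	PMAIP1	TP73	CASP3	CASP9	APAF1	BID
NUCLEOTIDE_POOL_SANITIZATION	synthetic curation: dNTP pool cleansing	NUDT1	DUT	ITPA	RRM2B	SAMHD1	NUDT15	NUDT18
CHROMATIN_REMODELING_AT_DSB	synthetic curation: remodellers recruited to breaks	SMARCA5	CHD3	CHD4	CHD1L	INO80	ACTR8	RUVBL1	RUVBL2	TRRAP	KAT5
HISTONE_UBIQUITINATION_SIGNALING	synthetic curation: RNF8/RNF168 axis	RNF8	RNF168	UBE2N	HERC2	RNF4	PIAS1	PIAS4	UIMC1	BABAM1	BRCC3	ABRAXAS1
ALTERNATIVE_END_JOINING	synthetic curation: POLQ-mediated MMEJ	POLQ	PARP1	LIG1	LIG3	XRCC1	FEN1	MRE11	RBBP8
TELOMERE_MAINTENANCE	synthetic curation: shelterin and telomerase	TERT	TERF1	TERF2	TERF2IP	TINF2	POT1	ACD	RTEL1	TNKS
TEMPLATE_SWITCHING_TOLERANCE	synthetic curation: PCNA polyubiquitination branch	HLTF	SHPRH	UBE2V2	UBE2N	RAD18	PCNA	ZRANB3	SPRTN
GLOBAL_GENOME_NER	synthetic curation: GG-NER damage sensing	XPC	RAD23B	DDB1	DDB2	CETN2	CUL4A	RBX1
TRANSCRIPTION_COUPLED_NER	synthetic curation: TC-NER	ERCC6	ERCC8	UVSSA	USP7	POLR2A	CUL4B
DOUBLE_STRAND_BREAK_REPAIR	synthetic curation: DSB repair umbrella	ATM	MRE11	RAD50	NBN	TP53BP1	BRCA1	BRCA2	RAD51	PRKDC	LIG4
REPLICATION_STRESS_RESPONSE	synthetic curation: stalled-fork signalling	ATR	CHEK1	RPA1	RPA2	TOPBP1	ETAA1	RAD9A	HUS1	RAD1	DONSON
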