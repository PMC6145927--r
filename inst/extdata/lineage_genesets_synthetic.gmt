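luminal	synthetic 25-gene luminal lineage set (editable fixture, not a curated signature)	KRT19	KRT8	KRT18	KRT7	GATA3	FOXA1	ESR1	XBP1	SPDEF	ELF3	EPCAM	CDH1	CLDN3	CLDN4	CLDN7	MUC1	AR	TFF1	TFF3	AGR2	ERBB3	GRHL2	RAB25	PRLR	KIT
myoepithelial	synthetic 25-gene myoepithelial/basal lineage set (editable fixture, not a curated signature)	KRT14	KRT5	KRT17	KRT6A	TP63	ACTA2	MYL9	TAGLN	CNN1	MYLK	OXTR	THY1	ITGA6	ITGB4	CAV1	CAV2	SPARC	LAMA3	LAMB3	COL17A1	DST	TRIM29	SFRP1	MME	EGFR
emt	synthetic 25-gene epithelial-mesenchymal transition set (editable fixture, not a curated signature)	VIM	CDH2	FN1	SNAI1	SNAI2	TWIST1	TWIST2	ZEB1	ZEB2	FOXC2	MMP2	MMP9	MMP3	TGFB1	TGFB2	SERPINE1	ITGB6	WNT5A	COL1A1	COL1A2	COL3A1	COL5A2	SPP1	MSN	AXL
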