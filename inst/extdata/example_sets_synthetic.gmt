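BASAL_LIKE_SYNTHETIC	synthetic stand-in for a basal-like subtype signature	KRT5	KRT14	S100A2	LY6D	FAM83A	SPRR3
CLASSICAL_SYNTHETIC	synthetic stand-in for a classical subtype signature	GATA6	TFF1	TFF2	LGALS4	AGR2	CEACAM6
PDAC_UP_SYNTHETIC	synthetic stand-in for tumor-upregulated genes	LDHA	ENO1	VEGFA	CA9	SLC2A1	MUC1	KRT19
HIF1A_TARGETS_SYNTHETIC	synthetic stand-in for HIF-1a transcriptional targets	LDHA	VEGFA	CA9	SLC2A1	PGK1	BNIP3
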