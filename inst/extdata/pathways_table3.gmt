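# Enriched pathways and their AMDgset candidate-gene lists,
# transcribed from the published pathway-enrichment table (24 rows).
# GMT: pathway_id <TAB> display name <TAB> member symbols...
COMPLEMENT_AND_COAGULATION_CASCADES	Complement and coagulation cascades	CFH	VTN	CFI	F13B	CFB	CFD	SERPING1	C2	C3	C4A	C9
FLUID_SHEAR_STRESS_AND_ATHEROSCLEROSIS	Fluid shear stress and atherosclerosis	HMOX1	HMOX2	GSTM1	NFE2L2	NQO1	CCL2	KDR	TNF	MMP2	MMP9	IL1B	NOS3	VEGFA
HIF_1_SIGNALING_PATHWAY	HIF–1 signaling pathway	FLT1	ANGPT2	HMOX1	TF	TFRC	IGF1R	TLR4	NOS2	NOS3	VEGFA
CYTOKINE_CYTOKINE_RECEPTOR_INTERACTION	Cytokine–cytokine receptor interaction	FLT1	IL17A	IL17RC	TNFRSF10A	CCR2	TGFBR1	CCL2	KDR	CCR3	TNF	IL1B	PRLR	CX3CR1	CXCL8	VEGFA
PLASMA_MEMBRANE_ESTROGEN_RECEPTOR_SIGNALING	Plasma membrane estrogen receptor signaling	ESR1	IGF1R	MMP2	MMP9	NOS3
CELLS_AND_MOLECULES_INVOLVED_IN_LOCAL_ACUTE_INFLAMMATORY_RES	Cells and Molecules involved in local acute inflammatory response	SELP	C3	TNF	CXCL8
PI3K_AKT_SIGNALING_PATHWAY	PI3K–Akt signaling pathway	COL4A3	FLT1	VTN	ANGPT2	PGF	RXRA	IGF1R	TLR2	TLR4	KDR	TNXB	NOS3	PRLR	VEGFA
IL23_MEDIATED_SIGNALING_EVENTS	IL23–mediated signaling events	IL17A	CCL2	TNF	IL1B	NOS2
PHAGOSOME	Phagosome	HLA-B	HLA-DQB1	TFRC	FCGR2A	CD36	SCARB1	TLR2	TLR4	C3
ENSEMBLE_OF_GENES_ENCODING_CORE_EXTRACELLULAR_MATRIX_INCLUDI	Ensemble of genes encoding core extracellular matrix including ECM glycoproteins, collagens and proteoglycans	COL4A3	COL8A1	COL10A1	FBLN5	VTN	COL15A1	GAS6	KERA	HMCN1	ELN	FGL1	TNXB
FAT_DIGESTION_AND_ABSORPTION	Fat digestion and absorption	ABCA1	CD36	SCARB1	NPC1L1	ABCG8
IL_17_SIGNALING_PATHWAY	IL–17 signaling pathway	IL17A	IL17RC	CCL2	TNF	MMP9	IL1B	CXCL8
GENES_ENCODING_ENZYMES_AND_THEIR_REGULATORS_INVOLVED_IN_THE_	Genes encoding enzymes and their regulators involved in the remodeling of the extracellular matrix	HTRA1	SERPINF1	MMP20	F13B	TIMP3	ADAMTS9	LOXL1	CST3	SERPING1	MMP2	MMP9
FREE_RADICAL_INDUCED_APOPTOSIS	Free Radical Induced Apoptosis	GPX1	TNF	CXCL8
INTEGRINS_IN_ANGIOGENESIS_AMB2_INTEGRIN_SIGNALING	Integrins in angiogenesis amb2 Integrin signaling	COL4A3	VTN	IGF1R	KDR	VEGFA
MINERAL_ABSORPTION	Mineral absorption	SELP	VTN	TNF	MMP2	MMP9
VEGF_HYPOXIA_AND_ANGIOGENESIS	VEGF, Hypoxia, and Angiogenesis	HMOX1	HMOX2	TF	MT2A	VDR
ADHESION_AND_DIAPEDESIS_OF_GRANULOCYTES	Adhesion and Diapedesis of Granulocytes	FLT1	KDR	NOS3	VEGFA
MECHANISM_OF_GENE_REGULATION_BY_PEROXISOME_PROLIFERATORS_VIA	Mechanism of Gene Regulation by Peroxisome Proliferators via PPARa(alpha)	SELP	TNF	CXCL8
CYTOKINES_CAN_INDUCE_ACTIVATION_OF_MATRIX_METALLOPROTEINASES	Cytokines can induce activation of matrix metalloproteinases, which degrade extracellular matrix	RXRA	PPARGC1A	CD36	TNF	NOS2
THE_IGF_1_RECEPTOR_AND_LONGEVITY	The IGF–1 Receptor and Longevity	ACE	TNF	IL1B
HIF_2_ALPHA_TRANSCRIPTION_FACTOR_NETWORK	HIF–2–alpha transcription factor network	IGF1R	SOD2	SOD3
TOLL_LIKE_RECEPTOR_SIGNALING_PATHWAY	Toll–like receptor signaling pathway	FLT1	SIRT1	KDR	VEGFA
ENSEMBLE_OF_GENES_ENCODING_ECM_ASSOCIATED_PROTEINS_INCLUDING	Ensemble of genes encoding ECM–associated proteins including ECM–affilaited proteins, ECM regulators and secreted factors	TLR2	TLR3	TLR4	TNF	IL1B	CXCL8
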