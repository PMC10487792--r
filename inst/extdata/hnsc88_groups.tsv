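group	gene
G1	APOBEC3A
G1	CMPK2
G1	DTX3L
G1	HERC5
G1	IFI30
G1	STAT1
G2	CXCL1
G2	IL1F9
G2	IL8
G2	MMP12
G2	MMP9
G3	DDX60
G3	GBP1
G3	IFI35
G3	IFI6
G3	IFIT1
G3	IFIT3
G3	ISG15
G3	RSAD2
G3	UBE2L6
G4	CTSL1
G4	NCF2
G4	RGS2
G4	SOD2
G4	TLR2
G5	COL4A1
G5	COL4A2
G5	COL5A1
G5	COL5A2
G5	CTHRC1
G5	PXDN
G6	INHBA
G6	LAMC2
G6	MMP1
G6	MMP10
G6	MMP3
G6	PLAU
G6	PTHLH
G6	TGFBI
G7	ACVR1
G7	CLIC4
G7	DSG2
G7	FAT1
G7	FNDC3B
G7	ITGAV
G7	SNAI2
G8	CDC45
G8	CDC6
G8	CDK4
G8	CHEK1
G8	CKS1B
G8	DTL
G8	FEN1
G8	FOXM1
G8	GINS1
G8	MCM2
G8	RFC4
G8	TPX2
G8	UHRF1
G9	AURKA
G9	BIRC5
G9	CDC20
G9	CEP55
G9	ECT2
G9	KIF2C
G9	KIF4A
G9	NUP155
G9	TRIP13
G10	CDH3
G10	CEBPB
G10	DFNA5
G10	GJA1
G10	HOMER3
G10	JUP
G10	KLF10
G10	KLF7
G10	KRT17
G10	MSN
G10	MYO1B
G10	PANX1
G10	PRNP
G10	RRAS2
G10	SLC16A1
G11	ACOT9
G11	FKBP9
G11	GALNT2
G11	UBE2Q2
G11	VKORC1
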