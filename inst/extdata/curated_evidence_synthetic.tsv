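GWAS_DATASET	QTL_TYPE	TISSUE	TOOL	GENE	SOURCE
SCZ_2014	eQTL	brain	FUSION	SNX19	CG
SCZ_2014	eQTL	brain	SMR	SNX19	CG
SCZ_2014	eQTL	brain	FUSION	KIAA0101	CG
SCZ_2018	eQTL	brain	FUSION	PCLAF	CG
SCZ_2018	sQTL	brain	FUSION	SNX19	CG
SCZ_2018	eQTL	blood	SMR	ZNF259	CG
SCZ_2022	eQTL	brain	SMR	PBXIP1	SG
SCZ_2022	mQTL	brain	SMR	PBXIP1	SG
SCZ_2022	eQTL	brain	FUSION	GRIN2A	SG
BP_2021	eQTL	brain	FUSION	RBM26	CG
BP_2021	sQTL	brain	FUSION	RBM26	CG
BP_2021	m6AQTL	brain	FUSION	RBM26	SG
BP_2021	eQTL	brain	SMR	PACSIN2	CG
BP_2021	sQTL	brain	SMR	PACSIN2	SG
BP_2021	pQTL	brain	SMR	PACSIN2	SG
BP_2021	mQTL	brain	SMR	PACSIN2	SG
ADHD_2019	eQTL	brain	SMR	ICA1L	CG
ADHD_2019	sQTL	brain	SMR	ICA1L	CG
ADHD_2019	mQTL	blood	SMR	ICA1L	SG
MDD_2019	eQTL	blood	SMR	DEC1	CG
MDD_2019	eQTL	brain	FUSION	BHLHE40	CG
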