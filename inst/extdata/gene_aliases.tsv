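ALIAS	CANONICAL
KIAA0101	PCLAF
C11orf30	EMSY
MARCH1	MARCHF1
MARCH2	MARCHF2
SEPT4	SEPTIN4
SEPT9	SEPTIN9
DEC1	BHLHE40
AIM1	CRYBG1
FAM46A	TENT5A
GPR56	ADGRG1
KIAA1598	SHTN1
C2orf47	MAIP1
WISP1	CCN4
WISP2	CCN5
NOV	CCN3
CTGF	CCN2
CYR61	CCN1
PVRL1	NECTIN1
PVRL2	NECTIN2
TMEM27	CLTRN
ADCK3	COQ8A
ADCK4	COQ8B
PAK7	PAK5
ZNF259	ZPR1
SNX19	SNX19
PCLAF	PCLAF
RBM26	RBM26
PACSIN2	PACSIN2
SUGP1	SUGP1
PBXIP1	PBXIP1
ICA1L	ICA1L
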