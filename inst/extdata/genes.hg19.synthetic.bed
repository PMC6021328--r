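chr7	54609000	54663000	VSTM2A	0	+
chr7	54820000	54826000	SEC61G	0	+
chr7	55086714	55324313	EGFR	0	+
chr7	55433000	55506000	LANCL2	0	+
chr7	55540000	55680000	VOPP1	0	+
chr12	57420000	57440000	ARHGEF25	0	+
chr12	57610000	57620000	PIP4K2C	0	+
chr12	57870000	57900000	MARS	0	+
chr12	57920000	57936000	DCTN2	0	+
chr12	57940000	57976000	KIF5A	0	+
chr12	57998000	58006000	DTX3	0	+
chr12	58009000	58014000	SLC26A10	0	+
chr12	58020000	58030000	B4GALNT1	0	+
chr12	58118000	58135000	AGAP2	0	+
chr12	58142000	58146000	CDK4	0	+
chr12	58156000	58161000	CYP27B1	0	+
chr12	58162000	58166000	METTL1	0	+
chr12	58168000	58174000	METT21B	0	+
chr12	58176000	58189000	TSFM	0	+
chr12	58191000	58211000	AVIL	0	+
chr12	58213000	58240000	CTDSP2	0	+
chr12	58250000	58277000	OS9	0	+
chr12	69201000	69239000	MDM2	0	+
chr12	69244000	69328000	CPM	0	+
chr12	69660000	69688000	ATP23	0	+
chr4	53001000	53481000	SCFD2	0	+
chr4	54240000	54320000	FIP1L1	0	+
chr4	55095264	55164414	PDGFRA	0	+
chr4	55524085	55606881	KIT	0	+
chr1	204042000	204096000	SOX13	0	+
chr1	204100000	204135000	ETNK2	0	+
chr1	204150000	204163000	REN	0	+
chr1	204190000	204196000	KISS1	0	+
chr1	204200000	204230000	GOLT1A	0	+
chr1	204240000	204300000	PLEKHA6	0	+
chr1	204400000	204470000	PIK3C2B	0	+
chr1	204485000	204527000	MDM4	0	+
chr1	204582000	204654000	LRRN2	0	+
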