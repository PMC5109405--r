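pharmacokinetic	synthetic reconstruction: drug metabolism and transport category (28 genes)	DPYD	TYMP	UPB1	UPP1	UPP2	CDA	ABCB1	ABCC1	ABCC2	ABCC3	ABCC4	ABCC5	ABCG2	SLC29A1	SLC29A2	SLC22A7	CES1	CES2	MTHFD1	SHMT1	CYP3A4	GSTP1	GSTM1	UGT1A1	NT5E	MTHFR	MTR	ATIC
purine_pyrimidine_metabolism	synthetic reconstruction: purine and pyrimidine metabolism category (47 genes)	TYMS	DHFR	TK1	TK2	RRM1	RRM2	RRM2B	POLA1	POLB	POLD1	POLE	PRPS1	PRPS2	PPAT	GART	PFAS	PAICS	ADSL	ADSS	IMPDH1	IMPDH2	GMPS	ADA	PNP	HPRT1	APRT	AK1	AK2	NME1	NME2	CTPS1	CTPS2	CAD	DHODH	UMPS	NT5C2	DCK	DCTD	DUT	ENTPD1	ITPA	AMPD1	AMPD2	AMPD3	GUK1	CMPK1	UCK1
fu_downstream_effectors	synthetic reconstruction: downstream 5-FU effector category, DNA repair / cell-cycle arrest / apoptosis (17 genes)	TP53	CDKN1A	BAX	BBC3	PMAIP1	CASP3	CASP8	CASP9	FAS	MYC	CHEK1	CHEK2	ATR	ATM	MDM2	BCL2	TP73
radio_response	synthetic reconstruction: radio-response, DNA-damage-related category (21 genes)	H2AFX	RAD51	RAD50	MRE11	NBN	XRCC1	XRCC2	XRCC3	XRCC4	XRCC5	XRCC6	PRKDC	LIG4	BRCA1	BRCA2	ERCC1	ERCC2	MLH1	MSH2	MSH6	PMS2
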