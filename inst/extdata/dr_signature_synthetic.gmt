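DR_POSITIVE	synthetic stand-in for the 220 positively DR-related genes	SIRT1	SIRT3	SIRT6	FOXO1	FOXO3	FOXO4	PRKAA1	PRKAA2	PRKAB1	PRKAG1	ATG5	ATG7	ATG12	BECN1	MAP1LC3B	ULK1	NFE2L2	SOD1	SOD2	CAT	GPX1	GSTP1	HMOX1	NQO1	PPARGC1A	PPARA	CREB1	CEBPB	KLOTHO1X	ADIPOQ	IGFBP1	IGFBP3	SESN1	SESN2	SESN3	TSC1	TSC2	STK11	DDIT4	EIF4EBP1	PTEN	TP53	CDKN1A	GADD45A	XRCC1	OGG1	APEX1	MLH1	MSH2	BRCA1	HSPA1A	HSPA5	HSPA8	HSPB1	DNAJB1	HSF1	UCP2	UCP3	CPT1A	ACOX1	ACADM	ACADL	HADHA	ECH1	LIPE	PNPLA2	ABHD5	FABP1	APOA1	APOE	DRSYNP001	DRSYNP002	DRSYNP003	DRSYNP004	DRSYNP005	DRSYNP006	DRSYNP007	DRSYNP008	DRSYNP009	DRSYNP010	DRSYNP011	DRSYNP012	DRSYNP013	DRSYNP014	DRSYNP015	DRSYNP016	DRSYNP017	DRSYNP018	DRSYNP019	DRSYNP020	DRSYNP021	DRSYNP022	DRSYNP023	DRSYNP024	DRSYNP025	DRSYNP026	DRSYNP027	DRSYNP028	DRSYNP029	DRSYNP030	DRSYNP031	DRSYNP032	DRSYNP033	DRSYNP034	DRSYNP035	DRSYNP036	DRSYNP037	DRSYNP038	DRSYNP039	DRSYNP040	DRSYNP041	DRSYNP042	DRSYNP043	DRSYNP044	DRSYNP045	DRSYNP046	DRSYNP047	DRSYNP048	DRSYNP049	DRSYNP050	DRSYNP051	DRSYNP052	DRSYNP053	DRSYNP054	DRSYNP055	DRSYNP056	DRSYNP057	DRSYNP058	DRSYNP059	DRSYNP060	DRSYNP061	DRSYNP062	DRSYNP063	DRSYNP064	DRSYNP065	DRSYNP066	DRSYNP067	DRSYNP068	DRSYNP069	DRSYNP070	DRSYNP071	DRSYNP072	DRSYNP073	DRSYNP074	DRSYNP075	DRSYNP076	DRSYNP077	DRSYNP078	DRSYNP079	DRSYNP080	DRSYNP081	DRSYNP082	DRSYNP083	DRSYNP084	DRSYNP085	DRSYNP086	DRSYNP087	DRSYNP088	DRSYNP089	DRSYNP090	DRSYNP091	DRSYNP092	DRSYNP093	DRSYNP094	DRSYNP095	DRSYNP096	DRSYNP097	DRSYNP098	DRSYNP099	DRSYNP100	DRSYNP101	DRSYNP102	DRSYNP103	DRSYNP104	DRSYNP105	DRSYNP106	DRSYNP107	DRSYNP108	DRSYNP109	DRSYNP110	DRSYNP111	DRSYNP112	DRSYNP113	DRSYNP114	DRSYNP115	DRSYNP116	DRSYNP117	DRSYNP118	DRSYNP119	DRSYNP120	DRSYNP121	DRSYNP122	DRSYNP123	DRSYNP124	DRSYNP125	DRSYNP126	DRSYNP127	DRSYNP128	DRSYNP129	DRSYNP130	DRSYNP131	DRSYNP132	DRSYNP133	DRSYNP134	DRSYNP135	DRSYNP136	DRSYNP137	DRSYNP138	DRSYNP139	DRSYNP140	DRSYNP141	DRSYNP142	DRSYNP143	DRSYNP144	DRSYNP145	DRSYNP146	DRSYNP147	DRSYNP148	DRSYNP149	DRSYNP150
DR_NEGATIVE	synthetic stand-in for the 56 negatively DR-related genes	FZD1	G6PD	MTOR	RPTOR	RICTOR	IGF1	IGF1R	INSR	IRS1	IRS2	AKT1	AKT2	PIK3CA	PIK3CB	MYC	CCND1	CDK4	E2F1	SREBF1	SREBF2	FASN	ACACA	SCD	HMGCR	LDLR	PKM	HK2	LDHA	GLUT1SL	VEGFA	DRSYNN001	DRSYNN002	DRSYNN003	DRSYNN004	DRSYNN005	DRSYNN006	DRSYNN007	DRSYNN008	DRSYNN009	DRSYNN010	DRSYNN011	DRSYNN012	DRSYNN013	DRSYNN014	DRSYNN015	DRSYNN016	DRSYNN017	DRSYNN018	DRSYNN019	DRSYNN020	DRSYNN021	DRSYNN022	DRSYNN023	DRSYNN024	DRSYNN025	DRSYNN026
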