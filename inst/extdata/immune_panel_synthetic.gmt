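ADC	synthetic marker-seeded immune panel set	CD1A	CD1B	CD1E	LAMP3	IMSYNC0101	IMSYNC0102	IMSYNC0103	IMSYNC0104	IMSYNC0105	IMSYNC0106	IMSYNC0107	IMSYNC0108
B_CELLS	synthetic marker-seeded immune panel set	CD19	MS4A1	CD79A	CD79B	IMSYNC0201	IMSYNC0202	IMSYNC0203	IMSYNC0204	IMSYNC0205	IMSYNC0206	IMSYNC0207	IMSYNC0208
CD8_T_CELLS	synthetic marker-seeded immune panel set	CD8A	CD8B	GZMK	CCL5	IMSYNC0301	IMSYNC0302	IMSYNC0303	IMSYNC0304	IMSYNC0305	IMSYNC0306	IMSYNC0307	IMSYNC0308
DC	synthetic marker-seeded immune panel set	ITGAX	CD83	HLA-DQA1	HLA-DQB1	IMSYNC0401	IMSYNC0402	IMSYNC0403	IMSYNC0404	IMSYNC0405	IMSYNC0406	IMSYNC0407	IMSYNC0408
IDC	synthetic marker-seeded immune panel set	CD1C	FCER1A	CLEC10A	ITGAM	IMSYNC0501	IMSYNC0502	IMSYNC0503	IMSYNC0504	IMSYNC0505	IMSYNC0506	IMSYNC0507	IMSYNC0508
MACROPHAGES	synthetic marker-seeded immune panel set	CD68	CD163	MSR1	MRC1	IMSYNC0601	IMSYNC0602	IMSYNC0603	IMSYNC0604	IMSYNC0605	IMSYNC0606	IMSYNC0607	IMSYNC0608
MAST_CELLS	synthetic marker-seeded immune panel set	TPSAB1	TPSB2	CPA3	MS4A2	IMSYNC0701	IMSYNC0702	IMSYNC0703	IMSYNC0704	IMSYNC0705	IMSYNC0706	IMSYNC0707	IMSYNC0708
NEUTROPHILS	synthetic marker-seeded immune panel set	FCGR3B	CSF3R	S100A8	S100A9	IMSYNC0801	IMSYNC0802	IMSYNC0803	IMSYNC0804	IMSYNC0805	IMSYNC0806	IMSYNC0807	IMSYNC0808
NK_CELLS	synthetic marker-seeded immune panel set	NCR1	KLRD1	KLRF1	NKG7	IMSYNC0901	IMSYNC0902	IMSYNC0903	IMSYNC0904	IMSYNC0905	IMSYNC0906	IMSYNC0907	IMSYNC0908
PDC	synthetic marker-seeded immune panel set	CLEC4C	LILRA4	IL3RA	IRF7	IMSYNC1001	IMSYNC1002	IMSYNC1003	IMSYNC1004	IMSYNC1005	IMSYNC1006	IMSYNC1007	IMSYNC1008
T_HELPER_CELLS	synthetic marker-seeded immune panel set	CD4	IL7R	CD28	ICOS	IMSYNC1101	IMSYNC1102	IMSYNC1103	IMSYNC1104	IMSYNC1105	IMSYNC1106	IMSYNC1107	IMSYNC1108
TFH	synthetic marker-seeded immune panel set	CXCR5	BCL6	PDCD1	IL21	IMSYNC1201	IMSYNC1202	IMSYNC1203	IMSYNC1204	IMSYNC1205	IMSYNC1206	IMSYNC1207	IMSYNC1208
TH1_CELLS	synthetic marker-seeded immune panel set	TBX21	IFNG	IL12RB2	STAT4	IMSYNC1301	IMSYNC1302	IMSYNC1303	IMSYNC1304	IMSYNC1305	IMSYNC1306	IMSYNC1307	IMSYNC1308
TH2_CELLS	synthetic marker-seeded immune panel set	GATA3	IL4	IL5	STAT6	IMSYNC1401	IMSYNC1402	IMSYNC1403	IMSYNC1404	IMSYNC1405	IMSYNC1406	IMSYNC1407	IMSYNC1408
TIL	synthetic marker-seeded immune panel set	CD3D	CD3E	CD3G	CD2	IMSYNC1501	IMSYNC1502	IMSYNC1503	IMSYNC1504	IMSYNC1505	IMSYNC1506	IMSYNC1507	IMSYNC1508
TREG	synthetic marker-seeded immune panel set	FOXP3	IL2RA	CTLA4	IKZF2	IMSYNC1601	IMSYNC1602	IMSYNC1603	IMSYNC1604	IMSYNC1605	IMSYNC1606	IMSYNC1607	IMSYNC1608
APC_CO_INHIBITION	synthetic marker-seeded immune panel set	PDCD1LG2	CD274	LGALS9	VTCN1	IMSYNP0101	IMSYNP0102	IMSYNP0103	IMSYNP0104	IMSYNP0105	IMSYNP0106	IMSYNP0107	IMSYNP0108
APC_CO_STIMULATION	synthetic marker-seeded immune panel set	CD40	CD80	CD86	ICOSLG	IMSYNP0201	IMSYNP0202	IMSYNP0203	IMSYNP0204	IMSYNP0205	IMSYNP0206	IMSYNP0207	IMSYNP0208
CCR	synthetic marker-seeded immune panel set	CCR1	CCR2	CCR5	CXCR4	IMSYNP0301	IMSYNP0302	IMSYNP0303	IMSYNP0304	IMSYNP0305	IMSYNP0306	IMSYNP0307	IMSYNP0308
CHECK_POINT	synthetic marker-seeded immune panel set	PDCD1	CTLA4	LAG3	HAVCR2	IMSYNP0401	IMSYNP0402	IMSYNP0403	IMSYNP0404	IMSYNP0405	IMSYNP0406	IMSYNP0407	IMSYNP0408
CYTOLYTIC_ACTIVITY	synthetic marker-seeded immune panel set	GZMA	PRF1	GZMB	GNLY	IMSYNP0501	IMSYNP0502	IMSYNP0503	IMSYNP0504	IMSYNP0505	IMSYNP0506	IMSYNP0507	IMSYNP0508
HLA	synthetic marker-seeded immune panel set	HLA-A	HLA-B	HLA-C	B2M	IMSYNP0601	IMSYNP0602	IMSYNP0603	IMSYNP0604	IMSYNP0605	IMSYNP0606	IMSYNP0607	IMSYNP0608
INFLAMMATION_PROMOTING	synthetic marker-seeded immune panel set	IL1B	IL6	TNF	PTGS2	IMSYNP0701	IMSYNP0702	IMSYNP0703	IMSYNP0704	IMSYNP0705	IMSYNP0706	IMSYNP0707	IMSYNP0708
MHC_CLASS_I	synthetic marker-seeded immune panel set	TAP1	TAP2	TAPBP	PSMB9	IMSYNP0801	IMSYNP0802	IMSYNP0803	IMSYNP0804	IMSYNP0805	IMSYNP0806	IMSYNP0807	IMSYNP0808
PARAINFLAMMATION	synthetic marker-seeded immune panel set	PLAT	SAA1	CFB	ISG15	IMSYNP0901	IMSYNP0902	IMSYNP0903	IMSYNP0904	IMSYNP0905	IMSYNP0906	IMSYNP0907	IMSYNP0908
T_CELL_CO_INHIBITION	synthetic marker-seeded immune panel set	BTLA	CD160	TIGIT	CD96	IMSYNP1001	IMSYNP1002	IMSYNP1003	IMSYNP1004	IMSYNP1005	IMSYNP1006	IMSYNP1007	IMSYNP1008
T_CELL_CO_STIMULATION	synthetic marker-seeded immune panel set	CD27	CD28I	TNFRSF9	TNFRSF18	IMSYNP1101	IMSYNP1102	IMSYNP1103	IMSYNP1104	IMSYNP1105	IMSYNP1106	IMSYNP1107	IMSYNP1108
TYPE_I_IFN_RESPONSE	synthetic marker-seeded immune panel set	IFIT1	IFIT3	MX1	OAS1	IMSYNP1201	IMSYNP1202	IMSYNP1203	IMSYNP1204	IMSYNP1205	IMSYNP1206	IMSYNP1207	IMSYNP1208
TYPE_II_IFN_RESPONSE	synthetic marker-seeded immune panel set	GBP1	GBP2	CXCL9	CXCL10	IMSYNP1301	IMSYNP1302	IMSYNP1303	IMSYNP1304	IMSYNP1305	IMSYNP1306	IMSYNP1307	IMSYNP1308
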