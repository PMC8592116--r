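locus_id	index_snp	secondary_signal	nearest_genes	top1	top1_score	top1_share	top1_is_nearest	top2	top2_score	top2_share	top2_is_nearest	top3	top3_score	top3_share	top3_is_nearest	nearest_gene_suspect
1q21.3-a	rs61813875	FALSE	CRCT1/LCE3E	HRNR	464	28	FALSE	RPTN	285	17	FALSE	CRNN	249	15	FALSE	FALSE
1q21.3-b	rs12730935	FALSE	IL-6R	IL-6R	743	62	TRUE	UBE2Q1	93	8	FALSE	ADAR	61	5	FALSE	FALSE
2p13.3	rs112111458	FALSE	CD207/VAX2	CD207	272	45	TRUE	CLEC4F	62	10	FALSE	VAX2	56	9	FALSE	FALSE
2q12.1	rs6419573,rs3917265	TRUE	IL-18R1/IL-18RAP	IL-18R1	1384	39	TRUE	IL-18RAP	1341	38	TRUE	IL1RL1	224	6	FALSE	FALSE
2q37.1	rs1057258	FALSE	INPP5D	INPP5D	296	57	TRUE	ATG16L1	106	20	FALSE	RN7SL32P	29	6	FALSE	FALSE
4q27	rs6827756,rs13152362	TRUE	KIAA1109	KIAA1109	220	35	TRUE	BBS12	112	18	FALSE	TRPC3	100	16	FALSE	FALSE
5p13.2	rs10214237	FALSE	IL-7R/CAPSL	IL-7R	965	65	TRUE	SPEF2	203	14	FALSE	UGT3A2	89	6	FALSE	FALSE
5q31.1-a	rs12188917	FALSE	TH2LCRR	SLC22A5	461	35	FALSE	IRF1	303	23	FALSE	RAD50	122	9	FALSE	FALSE
5q31.1-b	rs4705962	TRUE	KIF3A	KIF3A	249	23	TRUE	SLC22A5	247	23	FALSE	PDLIM4	142	13	FALSE	FALSE
6p21.32	rs4713555	FALSE	STAT3	HLA-DRA	1405	30	FALSE	HLA-DQB1	689	15	FALSE	HLA-DRB1	566	12	TRUE	TRUE
6p21.33	rs41293864	FALSE	MICB	HSPA1B	173	15	FALSE	HCG27	165	14	FALSE	CSNK2B	152	13	FALSE	FALSE
8q21.13	rs6473227	FALSE	MIR5708/ZBTB10	ZBTB10	192	41	TRUE	TPD52	70	15	FALSE	PAG1	69	15	FALSE	FALSE
10p15.1	rs6602364	FALSE	IL2RA/IL15RA	IL-2RA	333	45	TRUE	RBM17	111	15	FALSE	PFKFB3	51	7	FALSE	FALSE
10q21.2	rs2944542	FALSE	ZNF365	ADO	615	61	FALSE	ZNF365	101	10	TRUE	EGR2	90	9	FALSE	FALSE
11p13	rs2592555,rs12295535	TRUE	PRR5L	PRR5L	598	79	TRUE	TRAF6	65	9	FALSE	COMMD9	34	5	FALSE	FALSE
11q13.1	rs10791824	FALSE	OVOL1	CTSW	336	23	FALSE	OVOL1	236	16	TRUE	EFEMP2	168	11	FALSE	FALSE
11q13.5	rs2212434	FALSE	C11orf30/LRRC32	LRRC32	545	43	TRUE	EMSY	521	41	TRUE	THAP12	47	4	FALSE	FALSE
11q24.3	rs7127307	FALSE	-/ETS1	ETS1	298	75	TRUE	FLII	35	9	FALSE	APLP2	18	5	FALSE	FALSE
12q15	rs2227483	FALSE	IL22	MDM1	728	70	FALSE	IL-22	99	10	TRUE	IFNG	57	5	FALSE	FALSE
14q13.2	rs2038255	FALSE	PPP2R3C	PPP2R3C	996	31	TRUE	KIAA0391	814	25	FALSE	SRP54	433	13	FALSE	FALSE
14q32.32	rs7146581	FALSE	TRAF3	TRAF3	848	55	TRUE	AMN	281	18	FALSE	CDC42BPB	186	12	FALSE	FALSE
16p13.13	rs2041733	FALSE	CLEC16A	DEXI	376	34	FALSE	CLEC16A	364	33	TRUE	RMI2	108	10	FALSE	FALSE
17q21.2	rs12951971	FALSE	STAT3	DHX58	254	32	FALSE	STAT3	101	13	TRUE	RAB5C	100	13	FALSE	FALSE
17q25.3	rs11657987	FALSE	PGS1	PGS1	205	46	TRUE	DNAH17	73	16	FALSE	SOCS3	52	12	FALSE	FALSE
19p13.2	rs2918307	FALSE	ADAMTS10/ACTL9	ACTL9	115	41	TRUE	ADAMTS10	57	20	TRUE	MAP2K7	34	12	FALSE	FALSE
20q13.33	rs4809219	FALSE	RTEL1/TNFRSF6B	STMN3	608	27	FALSE	LIME1	473	21	FALSE	ARFRP1	257	12	FALSE	FALSE
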