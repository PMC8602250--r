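family	proband	family_history	gene	contig	pos	ref	alt	transcript	exon	cdna	protein	consequence	zygosity	af_global	af_afr	af_asj	af_eur_nf	af_amr	af_sas	popmax_af	popmax_pop	cadd	revel	evidence	printed_class	rsid	reference
FAM618	D815	familial	COL4A5	ChrX	108591636	G	A	NM_000495.5	21/51	c.1415G>A	p.Gly472Glu	missense_variant	1	0	NA	NA	0	NA	NA	0	none	24.1	0.9559	PM1, PM2, PM5, PP1, PP3, PP4	Likely pathogenic	NA	This study
FAM806	D1248	familial	DIAPH1	Chr5	141524214	C	T	NM_005219.5	27/28	c.3590G>A	p.Gly1197Asp	missense_variant	0/1	0	NA	NA	0	NA	NA	0	none	31	0.841	PM2, PP1, PP3	VUS	rs1354335913	This study
FAM411	D520	familial	MYO7A	Chr11	77192139	G	A	NM_000260.4	31/49	c.4013G>A	p.Arg1338His	missense_variant	0/1	1.97e-05	NA	NA	4.88e-06	6.539e-05	NA	6.539e-05	Latino/Admixed American	30	0.7559	PM2, PP3	VUS	rs778477059	This study
FAM837	D1321	sporadic	MYO15A	Chr17	18142122	G	A	NM_016239.4	24/66	c.5693G>A	p.Arg1898Gln	missense_variant	0/1	6.57e-06	0	NA	1.47e-05	NA	NA	1.47e-05	European (non-Finnish)	27.6	0.901	PM2, PM3, PP3	VUS	rs756752580	This study
FAM837	D1321	sporadic	MYO15A	Chr17	18153858	T	C	NM_016239.4	43/66	c.8050T>C	p.Tyr2684His	missense_variant	0/1	6.572e-05	NA	0.001729	1.171e-05	NA	NA	0.001729	Ashkenazi Jewish	26.2	0.837	PM3_S, PP1_S, PP3, BS1_P	Pathogenic	rs376351191	Bonnet et al.
FAM834	D1315	sporadic	OTOGL	Chr12	80255183	C	T	NM_173591.5	16/59	c.1558C>T	p.Gln520*	stop_gained	0/1	6.578e-05	NA	NA	0.0001178	NA	NA	0.0001178	European (non-Finnish)	49	NA	PVS1, PM3, PM2_P	Pathogenic	rs371465450	Bonnet et al.
FAM834	D1315	sporadic	OTOGL	Chr12	80320677	GGCCATCATCGAATCTCCGGAGGCAATTAGCCTATTCATGACCACATTCAAAGA	G	NM_173591.5	34/59	c.4032_4054+30del	p.?	splice_region_deletion	0/1	0	NA	NA	0	NA	NA	0	none	NA	NA	PVS1_S, PM2, PM3_P	Likely pathogenic	NA	This study
FAM417	D528	unknown	TECTA	Chr11	121127925	T	C	NM_005422.4	9/24	c.1948T>C	p.Cys650Arg	missense_variant	0/1	0	NA	NA	0	NA	NA	0	none	28.1	0.975	PM2, PP3	VUS	NA	This study
FAM642	D847	familial	TECTA	Chr11	121166767	G	A	NM_005422.4	18/24	c.5573G>A	p.Gly1858Glu	missense_variant	0/1	0	NA	NA	0	NA	NA	0	none	32	0.8169	PM2, PP3	VUS	NA	This study
FAM622	D821	familial	TECTA	Chr11	121168064	C	T	NM_005422.4	19/24	c.5597C>T	p.Thr1866Met	missense_variant	0/1	6.572e-06	NA	NA	1.47e-05	NA	NA	1.47e-05	European (non-Finnish)	30	0.7609	PS4, PP1_S, PM2, PP3	Pathogenic	rs140236996	published
FAM571	D753	familial	TECTA	Chr11	121168135	C	T	NM_005422.4	19/24	c.5668C>T	p.Arg1890Cys	missense_variant	0/1	0	NA	NA	0	NA	NA	0	none	27.8	0.7139	PP1_S, PM2, PS2_M, PS4_M, PP3	Pathogenic	rs121909063	published
FAM623	D822	familial	TECTA	Chr11	121168135	C	T	NM_005422.4	19/24	c.5668C>T	p.Arg1890Cys	missense_variant	0/1	0	NA	NA	0	NA	NA	0	none	27.8	0.7139	PP1_S, PM2, PS2_M, PS4_M, PP3	Pathogenic	rs121909063	published
FAM090	D103	unknown	TECTA	Chr11	121168751	A	G	NM_005422.4	20/24	c.5825A>G	p.Tyr1942Cys	missense_variant	0/1	0	NA	NA	0	NA	NA	0	none	29.6	0.896	PM2, PP3	VUS	rs373343675	This study
FAM200	D231	unknown	TECTA	Chr11	121190788	C	CTA	NM_005422.4	24/24	c.6449_6450insTA	p.Lys2150Asnfs*9	frameshift_variant	0/1	0	NA	NA	0	NA	NA	0	none	NA	NA	PM2, PM4	VUS	NA	This study
FAM416	D527	familial	TMC1	Chr9	72821027	C	T	NM_138691.3	20/24	c.1949C>T	p.Pro650Leu	missense_variant	0/1	0	NA	NA	0	NA	NA	0	none	26.9	0.54	PM2	VUS	NA	This study
FAM253	D298	sporadic	TMPRSS3	Chr21	42388935	G	A	NM_024022.3	4/13	c.316C>T	p.Arg106Cys	missense_variant	1/1	0.0001051	NA	NA	9.046e-05	NA	0.0004146	0.0004146	South Asian	27.9	0.7419	PM3, PP1_M, PP3, PM2_P	Likely pathogenic	rs139805921	Gao et al.
FAM174	D197	familial	TSPEAR	Chr21	44499923	C	A	NM_144991.3	12/12	c.1870G>T	p.Glu624*	stop_gained	1/1	1.314e-05	2.415e-05	NA	0	NA	NA	2.415e-05	African/African-American	49	NA	PVS1_M, PM2_P, PM3_P	VUS	rs587717339	This study
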