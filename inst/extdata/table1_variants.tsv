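# Six-variant fixture transcribing the published family prioritization table.
# Call quality and coverage were not published per variant; values here pass the QC stage by construction.
# Deleteriousness and intolerance panel calls realize the published favorable percentages.
Chrom	Pos	Ref	Alt	Gene	ExonicClassification	RegionClass	Qual	Depth	MAF_1KG	MAF_ExAC_nonTCGA	MAF_gnomAD_NFE	LocalCohortFreq	CADD_PHRED	GERP	PhyloP	PhastCons	Intolerance_InHouse	Intolerance_ESP	Intolerance_ExAC	ZScore	pLI	SIFT	Polyphen2_HumDiv	Polyphen2_HumVar	LRT	MutationTaster	MutationAssessor	FATHMM	MetaSVM	MetaLR	VEST3	PROVEAN	ReliabilityIndex	I-2	II-1	II-2	II-4	II-6	III-2	AminoAcidChange
19	8670022	C	T	ADAMTS10	nonsynonymous SNV	exonic	60	30	.	1.92E-05	8.95E-06	.	32	5.33	7.263	1	-1.02	-0.64	-0.33	2.1	0.12	D	D	P	D	D	L	T	D	D	0.88	N	4	0/1	0/1	0/1	0/1	0/1	0/0	V104M
2	70387896	G	C	C2orf42	nonsynonymous SNV	exonic	60	30	.	.	.	.	23.5	2.33	1.849	1	-0.41	0.22	-0.15	0.8	0.02	D	.	.	D	D	.	T	.	.	0.80	.	6	0/1	0/1	0/0	0/1	0/1	0/0	S459R
17	63049685	T	C	GNA13	nonsynonymous SNV	exonic	60	30	.	2.21E-04	3.33E-04	.	22.3	5.42	3.986	1	-0.52	0.31	-0.28	1.1	0.05	D	D	D	D	D	N	T	D	D	0.85	N	7	0/1	0/1	0/1	0/1	0/0	0/0	I149V
6	43100257	G	A	PTK7	nonsynonymous SNV	exonic	60	30	.	0	0.000	.	25.3	4.14	4.217	1	-1.20	-0.80	-0.50	1.5	0.97	D	D	P	D	D	L	T	D	D	0.90	N	4	0/1	0/1	0/1	0/1	0/0	0/0	V354M
7	77407669	G	A	RSBN1L	nonsynonymous SNV	exonic	60	30	.	0	0.000	.	35	5.94	7.575	1	-0.95	-0.71	-0.44	1.9	0.08	D	D	P	D	A	M	D	D	D	0.95	D	9	0/1	0/1	0/0	0/1	0/0	0/0	R603H
5	150431736	C	T	TNIP1	nonsynonymous SNV	exonic	60	30	.	1.86E-05	0.000	.	19.16	5.19	4.539	0.999	-0.33	0.18	-0.21	0.6	0.01	D	D	P	D	D	L	T	D	D	0.82	N	3	0/1	0/1	0/1	0/1	0/0	0/0	E238K
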