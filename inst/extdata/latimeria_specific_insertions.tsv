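insertion_id	te_type	species	length_nt	tsd	tsd_class	copy_total	copy_high98	transcript_hits	position_class	distance_kb	gene
1	CR1	L. chalumnae	1622	AT	TSD	5	2	17	IGR	5.9	HOXD12
2	CR1	L. chalumnae	1060		AT_rich_region	1	NA	0	intron	0.7	GRID1
3	CR1	L. chalumnae	1097	GAGTCTTGTT	TSD	1	NA	4	IGR	4.0	PCDHGC
4	CR1	L. chalumnae	227	CTA	TSD	49	5	1	IGR	9.7	ighv14-1 (21)
5	CR1	L. chalumnae	320	TTTAG	TSD	37	5	0	IGR	9.4	vomeronasal 2 receptor
6	CR1	L. chalumnae	303	TATTAGG	TSD	1	NA	0	IGR	>70.9	CALCOCO1
7	CR1	L. menadoensis	2845	ACTCA	TSD	23	4	24	IGR	>9.0	NA
8	CR1	L. menadoensis	2821	AAT	TSD	24	NA	31	IGR	3.2	PCDHGC5
9	CR1	L. menadoensis	1174	AAGTA	TSD	4	NA	8	IGR	3.6	PCDHGC5
10	CR1	L. menadoensis	1038	CCAT	TSD	74	18	10	IGR	18.3	protocadherin gamma
11	CR1	L. menadoensis	862	GATTAA	TSD	86	19	6	intron	0.2	SRA1
12	CR1	L. menadoensis	1398	TCTA	TSD	57	15	13	IGR	37.5	HOXB13
13	CR1	L. menadoensis	1019		polyA_region	1	NA	0	intron	1.3	PCDHGC
14	CR1	L. menadoensis	385		not_detected	110	14	0	intron	0.4	ighm
15	CR1	L. menadoensis	387	CTATTCC	TSD	109	12	3	intron	6.2	FAT tumor suppressor homolog
16	L1	L. menadoensis	2168	ACTAATCTTATTTTAA	TSD	2	2	20	IGR	41.6	hoxc1a
17	L1	L. menadoensis	1999		not_detected	4	NA	19	IGR	0.8	ighv14-1 (25)
18	L2	L. chalumnae	2219	G	TSD	2	NA	0	IGR	3.4	PCDHGC
19	CoeG-SINE	L. chalumnae	1362		not_detected	1	NA	16	intron	0.6	von Willebrand factor A domain containing 5A
20	CoeG-SINE	L. menadoensis	1018	ATTTT	TSD	1	NA	0	IGR	18.0	EVX2
21	LF-SINE	L. chalumnae	391	TG	TSD	48	NA	0	IGR	33.1	uncharacterized protein
22	Gypsy	L. chalumnae	896	CCCGCAGCGCCCCCCCCAGAGAAT	TSD	1	NA	1	IGR	33.1	uncharacterized protein
23	ERV	L. menadoensis	5091	AGAT	TSD	1	NA	41	IGR	10.6	ighv14-1 (21)
24	MITE-like	L. chalumnae	225	CCT	TSD	2	NA	0	IGR	6.4	von Willebrand factor A domain containing 5A
25	MITE-like	L. chalumnae	1311	ATTTCAAG	TSD	1	NA	5	IGR	2.8	CHRNB4
26	Composite	L. chalumnae	2303	T	TSD	1	NA	5	IGR	90.7	CRHR2
27	Composite	L. menadoensis	1249		not_detected	1	NA	0	IGR	>12.8	NA
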