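T°C Sample	Virotope Sequence	Viral target	CRISPR loci	Proto-spacer Start	Proto-spacer End	Mismatch position	SNV position	Alleles	Frequency of in CRISPR allele	SNV effect	Codon change
48	ACCTTTCAGACCTAACTCTAAAGTTACTATCACAGAT	Internal protein-M23-peptidase	48_CRISPR_2_NODE_1554	26558	26594	26564; 26567; 26582	–	–	–	–	–
58	AGAAGTTTTTCTTCGCCAAGATATATGGTGCTGGTCTAA	DNA polymerase	58_CRISPR_10_NODE_13413	282	320	–	282; 292; 313	G/T; C/A; G/A	0.079; 0.552; 0.549	All silent	CGA/AGA; GGG/CGT; TTC/TTT
58	GTGTTGGTGCTCTTGGAGTACCGTTCAGAATAGGT	Hypothetical protein	58_CRISPR_10_NODE_13413	35908	35942	–	35908	G/A	0.052	Silent	GGC/GGT
58	AGTTGTGCCCCTTGAGCTAGAGAATTTGCTGCACCT	Internal protein-M23-peptidase	58_CRISPR_10_NODE_13413	24692	24727	–	–	–	–	–	–
58	TAAACTGGTCGGGATTGTGTACATTCCATGCACTC	NC	58_CRISPR_10_NODE_13413	8740	8774	–	8753	C/G	0.53	–	–
58	ACTATCTGATCAAACCGGGGCTACACGGTAAATCGTTAGA	Tail fiber protein	58_CRISPR_10_NODE_13413	36649	36688	36650	36675	C/T	0.522	A/V	GCT/GTT
58	ACCTTTCAGACCTAACTCTAAAGTTACTATCACAGAT	Internal protein-M23-peptidase	58_CRISPR_5_NODE_1091	26558	26594	26565; 26567; 26582	–	–	–	–	–
58	CCCAACAACGTCTAAATAAATCTTTCTATGATATGC	Hypothetical protein	58_CRISPR_8_NODE_4438	24219	24254	24226; 24229; 24238	–	–	–	–	–
58	AATACGGTTGTAGTACTCTTGAAGAGGTGTTACCG	Hypothetical protein	58_CRISPR_8_NODE_4438	30971	31005	30972	30978	G/A	0.588	Silent	ACG/ACA
58	GAAAGGGTAAGGTGTCAAAATTGGGATTATTAGTGTTAG	Internal protein-M23-peptidase	58_CRISPR_8_NODE_4438	27172	27210	–	27180; 27181; 27186	T/A; C/A; A/C	0.626; 0.613; 0.575	S/T; S/Y; T/P	TCT/ACT; TCT/TAT; ACC/CCC
58	GCATTAATCGCGGGGTTAGGGTGATACCACCTA	Tail protein	58_CRISPR_8_NODE_4438	34211	34243	34214; 34226; 34241	–	–	–	–	–
58	TAGCTTAACATTACCACAGGGGATAAGCTGTTGTATATCC	Deoxycytidine triphosphate deaminase	58_CRISPR_9_NODE_4711	38225	38264	38264	38225; 38261	C/T G/A	0.057; 0.046	All silent	CTG/CTA; GAC; GAT
58	GACTTGATCTTTTCCGCTTTCTTGTAGCGCAGTATCTT	DNA polymerase	58_CRISPR_9_NODE_4711	668	705	–	671; 673	C/T; T/G	0.031; 0.040	R/K; Silent	AGG/AAG
58	ACGGGGTTGATCTTCCCCGCGAAGTGGTTGTCACCGAAT	dTMP kinase	58_CRISPR_9_NODE_4711	6338	6376	6375	6350	G/C	0.575	K/N	AAG/AAC
58	AAATACATCCCCCACTTTAGGAGGTAACCCCAC	Hypothetical protein	58_CRISPR_9_NODE_4711	36127	36159	–	–	–	–	–	–
58	ACAGCGAAAGCAATTTGTCTCTGAGGCTAACAAGTT	Internal protein-M23-peptidase	58_CRISPR_9_NODE_4711	25742	25777	25776	–	–	–	–	–
58	GTCGTATCTCAATGTACTCTTTGTAGTCTTTCCA	Internal protein-M23-peptidase	58_CRISPR_9_NODE_4711	25917	25950	–	25946	C/A	0.041	Silent	ATC/ATA
58	CAATCACACCTAACCCCATAGGTGACCGCACAACA	Portal protein	58_CRISPR_9_NODE_4711	15920	15954	–	15941; 15953	A/G; A/T	0.651; 0.055	All silent	GGA/GGG; ATA/ATT
58	TAGCTGATTGGAAAGCAGACGCTGGATTATTACAC	Tail protein	58_CRISPR_9_NODE_4711	33859	33893	–	–	–	–	–	–
66	ATCTGTGATAGTAACTTTAGAGTTAGGTCTGAAAGGT	Internal protein-M23-peptidase	66_CRISPR_2_NODE_1045	26558	26594	26566; 26567; 26582	–	–	–	–	–
66	TTAGACCAGCACCATATATCTTGGCGAAGAAAAACTTCT	DNA polymerase	66_CRISPR_3_NODE_1491	282	320	282	292; 313	C/A; G/A	0.437; 0.024	All silent	GGG/CGT; TTC/TTT
66	ACCTATTCTGAACGGTACTCCAAGAGCACCAACAC	Hypothetical protein	66_CRISPR_3_NODE_1491	35908	35942	35908	–	–	–	–	–
66	AGGTGCAGCAAATTCTCTAGCTCAAGGGGCACAACT	Internal protein-M23-peptidase	66_CRISPR_3_NODE_1491	24692	24727	–	–	–	–	–	–
66	GAGTGCATGGAATGTACACAATCCCGACCAGTTTA	NC	66_CRISPR_3_NODE_1491	8740	8774	–	8753	C/G	0.051	–	–
66	TCTAACGATTTACCGTGTAGCCCCGGTTTGATCAGATAGT	Tail fiber protein	66_CRISPR_3_NODE_1491	36649	36688	36650	36675	C/T	0.056	A/V	GCT/GTT
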