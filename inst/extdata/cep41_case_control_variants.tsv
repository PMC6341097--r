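chrom	pos	ref	alt	gene	aa_change	functional_class	case_obs	control_obs	in_dbsnp	in_1kg_eur	in_esp_ea	af_1kg_eur	sift	polyphen2	gerp	cadd_phred
7	130038866	C	G	CEP41	A330P	nonsynonymous	1	0	NA	NA	NA	NA	0.12	0.06	2.66	7.084
7	130040580	C	T	CEP41	R242H	nonsynonymous	1	0	NA	NA	NA	NA	0.04	0.998	6.03	34
7	130041748	G	C	CEP41	P206A	nonsynonymous	12	1	NA	NA	NA	NA	0.14	0.997	5.54	23.3
7	130041754	T	C	CEP41	M204V	nonsynonymous	1	0	NA	NA	NA	NA	0.15	0.64	5.54	18.04
7	130041762	G	C	CEP41	S201C	nonsynonymous	1	0	NA	NA	NA	NA	0.03	0.997	5.54	21.9
7	130044507	G	C	CEP41	A107G	nonsynonymous	0	1	NA	NA	NA	NA	0.39	0.116	0.835	10.79
7	130050987	C	G	CEP41	A85P	nonsynonymous	1	0	NA	NA	NA	NA	0.28	0.773	3.18	15.08
7	130056798	A	G	CEP41	M36T	nonsynonymous	1	0	NA	NA	NA	NA	0.30	NA	5.71	13.96
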