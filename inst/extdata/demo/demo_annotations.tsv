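chrom	pos	ref	alt	gene_symbol	consequence	sift	polyphen2	provean	cadd_phred	vqsr_score
chr1	1100	G	A	DEMO1	splice_acceptor	missing	missing	missing	25.3	62.1
chr1	1200	C	T	DEMO1	splice_donor	missing	missing	missing	31.0	58.4
chr1	1300	A	G	DEMO1	start_lost	missing	missing	missing	NA	71.9
chr1	1400	C	G	DEMO1	stop_gained	missing	missing	missing	NA	66.0
chr1	2000	G	A	DEMO1	missense	damaging	damaging	damaging	NA	55.2
chr1	2100	C	T	DEMO1	missense	damaging	damaging	tolerated	NA	49.7
chr1	2200	T	C	DEMO1	missense	damaging	tolerated	missing	NA	80.3
chr1	2300	G	T	DEMO1	missense	damaging	missing	missing	NA	NA
chr1	2400	A	C	DEMO1	missense	damaging	damaging	missing	NA	59.5
chr1	2500	G	A	DEMO1	missense	tolerated	damaging	damaging	NA	61.8
chr1	30100	C	T	DEMO2	missense	tolerated	tolerated	tolerated	NA	72.4
chr1	30200	G	A	DEMO2	missense	damaging	tolerated	tolerated	NA	68.1
chr1	30300	A	G	DEMO2	missense	tolerated	tolerated	missing	NA	54.9
chr1	30400	T	C	DEMO2	missense	tolerated	missing	missing	NA	NA
chr1	30500	C	A	DEMO2	missense	tolerated	damaging	tolerated	NA	77.2
chr1	31000	G	A	DEMO2	intronic	missing	missing	missing	NA	63.3
chr1	31100	C	T	DEMO2	intronic	missing	missing	missing	NA	59.0
chr1	31200	T	G	DEMO2	intronic	missing	missing	missing	NA	70.6
chr1	31300	A	T	DEMO2	upstream	missing	missing	missing	NA	65.7
chr1	31400	G	C	DEMO2	downstream	missing	missing	missing	NA	52.8
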