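##fileformat=VCFv4.2
##INFO=<ID=AF,Number=A,Type=Float,Description="Allele Frequency">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO
chr1	1100	rs1001	G	A	.	.	AF=0.0001
chr1	1200	rs1002	C	T	.	.	AF=0.005
chr1	1300	.	A	G	.	.	AF=0.002
chr1	1400	rs1004	C	G	.	.	AF=0.0871
chr1	2000	rs1005	G	A	.	.	AF=0.001
chr1	2100	rs1006	C	T	.	.	AF=0.003
chr1	2200	rs1007	T	C	.	.	AF=0.008
chr1	2300	.	G	T	.	.	AF=0.0005
chr1	2400	rs1009	A	C	.	.	AF=0.02
chr1	2500	rs1010	G	A	.	.	AF=0.15
chr1	30100	rs2001	C	T	.	.	AF=0.05
chr1	30200	rs2002	G	A	.	.	AF=0.10
chr1	30300	rs2003	A	G	.	.	AF=0.20
chr1	30400	rs2004	T	C	.	.	AF=0.30
chr1	30500	rs2005	C	A	.	.	AF=0.40
chr1	31000	rs2006	G	A	.	.	AF=0.03
chr1	31100	rs2007	C	T	.	.	AF=0.12
chr1	31200	rs2008	T	G	.	.	AF=0.25
chr1	31300	rs2009	A	T	.	.	AF=0.33
chr1	31400	rs2010	G	C	.	.	AF=0.45
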