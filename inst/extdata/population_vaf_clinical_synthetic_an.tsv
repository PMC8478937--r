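gene_symbol	rsid	chrom	pos	ref	alt	population	vaf	n_alleles
ABCC4	rs2274407	chr13	95859035	C	A	African	0.167	41440
ABCC4	rs2274407	chr13	95859035	C	A	Ashkenazi_Jewish	0.1325	3470
ABCC4	rs2274407	chr13	95859035	C	A	Amish	0.01429	912
ABCC4	rs2274407	chr13	95859035	C	A	Middle_Eastern	0.121	316
ABCC4	rs2274407	chr13	95859035	C	A	Latino	0.08122	15294
ABCC4	rs2274407	chr13	95859035	C	A	European_nonFinnish	0.06825	68058
ABCC4	rs2274407	chr13	95859035	C	A	European_Finnish	0.06309	21632
ABCC4	rs2274407	chr13	95859035	C	A	East_Asian	0.1759	5208
ABCC4	rs2274407	chr13	95859035	C	A	South_Asian	0.1456	4838
ABCC4	rs2274407	chr13	95859035	C	A	CMDB_Chinese	0.126	282862
ABCC4	rs11568658	chr13	95863008	C	A	African	0.004779	41440
ABCC4	rs11568658	chr13	95863008	C	A	Ashkenazi_Jewish	0.0415	3470
ABCC4	rs11568658	chr13	95863008	C	A	Amish	0.1404	912
ABCC4	rs11568658	chr13	95863008	C	A	Middle_Eastern	0.05063	316
ABCC4	rs11568658	chr13	95863008	C	A	Latino	0.08711	15294
ABCC4	rs11568658	chr13	95863008	C	A	European_nonFinnish	0.02346	68058
ABCC4	rs11568658	chr13	95863008	C	A	European_Finnish	0.04566	21632
ABCC4	rs11568658	chr13	95863008	C	A	East_Asian	0.1146	5208
ABCC4	rs11568658	chr13	95863008	C	A	South_Asian	0.05763	4838
ABCC4	rs11568658	chr13	95863008	C	A	CMDB_Chinese	0.1155	282862
SLCO1B1	rs4149056	chr12	21331549	T	C	African	0.03168	41440
SLCO1B1	rs4149056	chr12	21331549	T	C	Ashkenazi_Jewish	0.1771	3470
SLCO1B1	rs4149056	chr12	21331549	T	C	Amish	0.06798	912
SLCO1B1	rs4149056	chr12	21331549	T	C	Middle_Eastern	0.2057	316
SLCO1B1	rs4149056	chr12	21331549	T	C	Latino	0.13	15294
SLCO1B1	rs4149056	chr12	21331549	T	C	European_nonFinnish	0.1587	68058
SLCO1B1	rs4149056	chr12	21331549	T	C	European_Finnish	0.2178	21632
SLCO1B1	rs4149056	chr12	21331549	T	C	East_Asian	0.1279	5208
SLCO1B1	rs4149056	chr12	21331549	T	C	South_Asian	0.04888	4838
SLCO1B1	rs4149056	chr12	21331549	T	C	CMDB_Chinese	0.1085	282862
ALDH2	rs671	chr12	112241766	G	A	African	0.0001931	41440
ALDH2	rs671	chr12	112241766	G	A	Ashkenazi_Jewish	0	3470
ALDH2	rs671	chr12	112241766	G	A	Amish	0	912
ALDH2	rs671	chr12	112241766	G	A	Middle_Eastern	0	316
ALDH2	rs671	chr12	112241766	G	A	Latino	0.0009178	15294
ALDH2	rs671	chr12	112241766	G	A	European_nonFinnish	2.94e-05	68058
ALDH2	rs671	chr12	112241766	G	A	European_Finnish	9.436e-05	21632
ALDH2	rs671	chr12	112241766	G	A	East_Asian	0.2247	5208
ALDH2	rs671	chr12	112241766	G	A	South_Asian	0.0008292	4838
ALDH2	rs671	chr12	112241766	G	A	CMDB_Chinese	0.2021	282862
TPMT	rs1142345	chr6	18130918	T	C	African	0.05485	41440
TPMT	rs1142345	chr6	18130918	T	C	Ashkenazi_Jewish	0.01902	3470
TPMT	rs1142345	chr6	18130918	T	C	Amish	0.0165	912
TPMT	rs1142345	chr6	18130918	T	C	Middle_Eastern	0.02532	316
TPMT	rs1142345	chr6	18130918	T	C	Latino	0.05058	15294
TPMT	rs1142345	chr6	18130918	T	C	European_nonFinnish	0.04227	68058
TPMT	rs1142345	chr6	18130918	T	C	European_Finnish	0.0293	21632
TPMT	rs1142345	chr6	18130918	T	C	East_Asian	0.01366	5208
TPMT	rs1142345	chr6	18130918	T	C	South_Asian	0.01863	4838
TPMT	rs1142345	chr6	18130918	T	C	CMDB_Chinese	0.01291	282862
UGT1A1	rs34946978	chr2	234676872	C	T	African	0.0002171	41440
UGT1A1	rs34946978	chr2	234676872	C	T	Ashkenazi_Jewish	0	3470
UGT1A1	rs34946978	chr2	234676872	C	T	Amish	0	912
UGT1A1	rs34946978	chr2	234676872	C	T	Middle_Eastern	0	316
UGT1A1	rs34946978	chr2	234676872	C	T	Latino	0.001767	15294
UGT1A1	rs34946978	chr2	234676872	C	T	European_nonFinnish	2.94e-05	68058
UGT1A1	rs34946978	chr2	234676872	C	T	European_Finnish	0	21632
UGT1A1	rs34946978	chr2	234676872	C	T	East_Asian	0.01196	5208
UGT1A1	rs34946978	chr2	234676872	C	T	South_Asian	0.001242	4838
UGT1A1	rs34946978	chr2	234676872	C	T	CMDB_Chinese	0.01986	282862
VDR	rs2228570	chr12	48272895	A	G	African	0.7799	41440
VDR	rs2228570	chr12	48272895	A	G	Ashkenazi_Jewish	0.5716	3470
VDR	rs2228570	chr12	48272895	A	G	Amish	0.7368	912
VDR	rs2228570	chr12	48272895	A	G	Middle_Eastern	0.7025	316
VDR	rs2228570	chr12	48272895	A	G	Latino	0.5778	15294
VDR	rs2228570	chr12	48272895	A	G	European_nonFinnish	0.6162	68058
VDR	rs2228570	chr12	48272895	A	G	European_Finnish	0.644	21632
VDR	rs2228570	chr12	48272895	A	G	East_Asian	0.5698	5208
VDR	rs2228570	chr12	48272895	A	G	South_Asian	0.7387	4838
VDR	rs2228570	chr12	48272895	A	G	CMDB_Chinese	0.5141	282862
NUDT15	rs186364861	chr13	48611934	G	A	African	0	41440
NUDT15	rs186364861	chr13	48611934	G	A	Ashkenazi_Jewish	0.000288	3470
NUDT15	rs186364861	chr13	48611934	G	A	Amish	0	912
NUDT15	rs186364861	chr13	48611934	G	A	Middle_Eastern	0	316
NUDT15	rs186364861	chr13	48611934	G	A	Latino	0	15294
NUDT15	rs186364861	chr13	48611934	G	A	European_nonFinnish	1.47e-05	68058
NUDT15	rs186364861	chr13	48611934	G	A	European_Finnish	0	21632
NUDT15	rs186364861	chr13	48611934	G	A	East_Asian	0.01121	5208
NUDT15	rs186364861	chr13	48611934	G	A	South_Asian	0.0008271	4838
NUDT15	rs186364861	chr13	48611934	G	A	CMDB_Chinese	0.01607	282862
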