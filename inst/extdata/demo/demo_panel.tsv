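symbol	family	chrom	start	end
DEMO1	ABC	chr1	1000	20999
DEMO2	SLC	chr1	30000	49999
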