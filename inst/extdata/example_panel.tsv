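snp_id	chrom	pos	ref_allele	alt_allele	mappability
rsA	chr1	105	A	G	1
rsB	chr1	205	C	T	1
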