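@HD	VN:1.6	SO:coordinate
@SQ	SN:chr1	LN:1000
s2	0	chr1	99	50	10M	*	0	0	CCCCCCACCC	*	NH:i:1
s1	0	chr1	100	50	10M	*	0	0	CCCCCACCCC	*	NH:i:1
s3	0	chr1	100	50	10M	*	0	0	CCCCCACCCC	*	NH:i:1
s5	0	chr1	100	50	10M	*	0	0	CCCCCGCCCC	*	NH:i:1
s4	0	chr1	102	50	10M	*	0	0	CCCACCCCCC	*	NH:i:1
s6	0	chr1	200	50	10M	*	0	0	AAAAACAAAA	*	NH:i:1
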