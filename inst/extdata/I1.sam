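@HD	VN:1.6	SO:coordinate
@SQ	SN:chr1	LN:1000
r2	0	chr1	98	50	10M	*	0	0	GGGGGGGAGG	*	NH:i:1
r1	0	chr1	100	50	10M	*	0	0	CCCCCACCCC	*	NH:i:1
r4	0	chr1	100	50	10M	*	0	0	CCCCCGCCCC	*	NH:i:1
r6	0	chr1	100	50	10M	*	0	0	CCCCCTCCCC	*	NH:i:1
r7	0	chr1	100	50	10M	*	0	0	CCCCCACCCC	*	NH:i:2
r3	0	chr1	101	50	10M	*	0	0	TTTTATTTTT	*	NH:i:1
r5	0	chr1	103	50	10M	*	0	0	GGGGGGGGGG	*	NH:i:1
r9	0	chr1	198	50	5S10M	*	0	0	AAAAAAAAAAAACAA	*	NH:i:1
r8	0	chr1	200	50	10M	*	0	0	AAAAACAAAA	*	NH:i:1
r10	0	chr1	200	50	10M	*	0	0	AAAAATAAAA	*	NH:i:1
r12	0	chr1	200	50	3M4D5M	*	0	0	AAAAAAAA	*	NH:i:1
r11	0	chr1	203	50	10M	*	0	0	GGTGGGGGGG	*	NH:i:1
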