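individual_id	rsA	rsB
I1	1	1
I2	1	0
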