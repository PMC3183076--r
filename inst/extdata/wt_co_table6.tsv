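# kind=CO
# mode=wt
# table=6
# total=282
pattern	occurrence	chromatid_assignment	printed_class
none	62	none	.
3:1	194	unspecified	.
3:1_2:2	8	unspecified	.
3:1_1:3	4	unspecified	.
3:1_2:2_3:1	11	unspecified	.
3:1_2:2_3:1*_2:2	1	unspecified	.
3:1_2:2_1:3_2:2*_1:3	1	unspecified	.
3:1_2:2_3:1_2:2_3:1_2:2_3:1	1	unspecified	.
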