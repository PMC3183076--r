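# kind=CO
# mode=msh2
# table=4
# total=181
pattern	occurrence	chromatid_assignment	printed_class
none	26	none	.
2:6	26	single	.
3:5	16	single	.
4:4*	1	two-non-sister	.
3:5_2:6	15	single	.
3:5_4:4	7	single	.
2:6_4:4	5	single	.
3:5_4:4*	4	two-non-sister	.
5:3_5:3*	1	single	.
3:5_5:3	2	single	.
5:3_2:6	1	single	.
3:5_4:4_3:5	2	single	.
2:6_4:4_2:6	4	single	.
3:5_4:4_2:6	5	single	.
2:6_3:5_4:4	2	single	.
3:5_2:6_3:5*	3	two-non-sister	.
3:5_4:4_3:5*	2	two-non-sister	.
2:6_4:4*_3:5	1	two-non-sister	.
4:4*_3:5_3:5*	1	two-non-sister	.
5:3_5:3*_6:2	2	two-non-sister	.
3:5_4:4_5:3	2	single	.
3:5_6:2_5:3	1	single	.
2:6_3:5_5:3	1	single	.
6:2_4:4_3:5	2	single	.
>3	27	single	.
>3	22	two-non-sister	.
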