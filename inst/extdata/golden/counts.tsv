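contig	position	C1	C2	C3	T2	T3	T4
chr1	110	10	10	10	10	10	10
chr1	140	20	24	30	8	6	4
chr1	200	2	1	0	2	1	0
chr1	300	40	44	50	12	10	6
chr1	660	30	36	40	10	8	2
chr1	900	60	60	60	70	80	90
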