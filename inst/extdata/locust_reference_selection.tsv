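transcript_id	direction	ratio
SCH_0145	increased	1.689
SCH_0029	increased	1.799
SCH_0092	increased	1.947
SCH_0447	increased	2.180
SCH_0448	increased	2.546
SCH_0387	increased	2.996
SCH_0350	increased	3.020
SCH_0324	increased	3.038
SCH_0044	decreased	0.069
SCH_0474	decreased	0.071
SCH_0227	decreased	0.072
SCH_0208	decreased	0.072
SCH_0228	decreased	0.096
SCH_0426	decreased	0.106
SCH_0362	decreased	0.217
SCH_0332	decreased	0.221
SCH_0255	decreased	0.255
SCH_0233	decreased	0.293
SCH_0015	decreased	0.310
SCH_0397	decreased	0.317
SCH_0215	decreased	0.373
SCH_0199	decreased	0.390
SCH_0467	decreased	0.418
SCH_0288	decreased	0.427
SCH_0247	decreased	0.444
SCH_0163	decreased	0.457
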