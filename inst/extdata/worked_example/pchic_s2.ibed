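bait_chr	bait_start	bait_end	bait_name	otherEnd_chr	otherEnd_start	otherEnd_end	otherEnd_name	N_reads	score
chr1	4000	6000	g1	chr1	12000	12800	.	0	6
chr1	4000	6000	g1	chr1	24000	26000	.	0	8
chr1	24000	26000	g2	chr1	32000	32800	.	0	5.2
chr1	44000	46000	g3	chr1	4000	6000	.	0	7
chr1	64000	66000	g4	chr1	75000	75800	.	0	6
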