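chr1	4000	6000	chr1	12000	12800	chr1:4000-6000__chr1:12000-12800	5
chr1	4000	6000	chr1	24000	26000	chr1:4000-6000__chr1:24000-26000	3
chr1	12000	12800	chr1	32000	32800	chr1:12000-12800__chr1:32000-32800	2
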