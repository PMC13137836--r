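experiment	dose_a	dose_b	signal
exp_1	0	0	1000
exp_1	0	1	600
exp_1	1	0	500
exp_1	1	1	100
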