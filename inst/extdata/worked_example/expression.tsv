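gene_id	dmso_1	dmso_2
g1	50	52
g2	64	60
g3	20	22
g4	30	28
g5	12	14
g6	2	2
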