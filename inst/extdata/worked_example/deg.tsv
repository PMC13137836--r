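gene_id	log2fc	padj
g1	1.5	0.01
g2	-2	0.01
g3	0.5	0.001
g4	-1.5	0.2
g5	0	0.9
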