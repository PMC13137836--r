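chrom	txStart	txEnd	strand	gene_id
chr1	5000	7000	+	g1
chr1	25000	27000	+	g2
chr1	45000	47000	+	g3
chr1	65000	67000	+	g4
chr1	85000	87000	+	g5
chr1	105000	107000	+	g6
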