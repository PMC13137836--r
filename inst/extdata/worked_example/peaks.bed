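chr1	4600	5400
chr1	24600	25400
chr1	44600	45400
chr1	64600	65400
chr1	84600	85400
chr1	12000	12800
chr1	32000	32800
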