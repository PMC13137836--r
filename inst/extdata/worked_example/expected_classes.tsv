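gene_id	promoter_class	n_epi	n_ppi	has_any_interaction
g1	EPI_AND_PPI	1	1	TRUE
g2	EPI_ONLY	1	0	TRUE
g3	PPI_ONLY	0	1	TRUE
g4	NO_ACTIVE_OE	0	0	TRUE
g5	NO_ACTIVE_OE	0	0	FALSE
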