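species	genes_with_introns	total_introns	min_bp	max_bp	mean_bp
pea_aphid	26	34	62	30718	4193
fruit_fly	18	20	57	11845	1082
honey_bee	9	9	72	4460	1326
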