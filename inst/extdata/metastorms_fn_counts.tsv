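threshold	total_pairs	differing_pairs
0.05	28247	351
0.10	96977	1402
0.20	846107	14993
0.30	4847874	91902
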