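cluster	n_samples	n_aggressive_enrichments	n_non_aggressive_enrichments
LAYC	189	0	11
MAYC	132	7	4
LAAC	103	5	4
MAAC	57	12	0
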