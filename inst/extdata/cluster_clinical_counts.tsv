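parameter	level	aggressive	LAYC	MAYC	LAAC	MAAC
lymph_node_metastasis	N0	no	90	41	67	21
lymph_node_metastasis	N1	yes	77	80	26	33
tumor_size_1cm	lt_1cm	no	62	36	32	20
tumor_size_1cm	ge_1cm	yes	127	96	71	37
tumor_size_2cm	lt_2cm	no	137	103	75	35
tumor_size_2cm	ge_2cm	yes	52	29	28	22
extrathyroidal_extension	absent	no	151	80	66	25
extrathyroidal_extension	present	yes	33	50	30	32
ete_gross	no_gross	no	184	128	90	47
ete_gross	gross	yes	0	2	6	10
distant_metastasis	M0	no	97	81	57	31
distant_metastasis	M1	yes	3	1	2	3
histotype_fptc	FPTC	no	62	4	30	4
histotype_fptc	C_TPTC	yes	123	124	72	53
histotype_tptc	C_FPTC	no	183	113	97	44
histotype_tptc	TPTC	yes	2	15	5	13
braf_mutation	WT	no	56	3	28	3
braf_mutation	MUT	yes	64	93	37	39
tert_mutation	WT	no	145	98	67	27
tert_mutation	MUT	yes	2	5	11	18
differentiation_score	high	no	98	17	54	12
differentiation_score	low	yes	54	93	28	34
disease_free_survival	non_recurrence	no	177	120	89	37
disease_free_survival	recurrence	yes	11	13	8	12
overall_survival	alive	no	188	133	97	47
overall_survival	dead	yes	0	0	6	10
progression_free_interval	non_recurrence	no	177	120	91	43
progression_free_interval	recurrence	yes	11	13	11	14
disease_specific_survival	alive	no	188	133	98	48
disease_specific_survival	dead	yes	0	0	3	4
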