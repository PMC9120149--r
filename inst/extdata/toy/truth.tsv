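og_id	family_id	column	phase	true_leca
fam1_og1	fam1	13	2	FALSE
fam1_og1	fam1	15	0	TRUE
fam1_og1	fam1	17	2	TRUE
fam1_og1	fam1	19	2	TRUE
fam1_og1	fam1	21	0	TRUE
fam1_og1	fam1	25	1	TRUE
fam1_og1	fam1	36	2	TRUE
fam1_og1	fam1	38	0	TRUE
fam1_og1	fam1	42	0	TRUE
fam1_og1	fam1	57	0	TRUE
fam1_og1	fam1	57	2	TRUE
fam1_og1	fam1	59	0	TRUE
fam1_og2	fam1	10	0	TRUE
fam1_og2	fam1	14	2	TRUE
fam1_og2	fam1	16	0	TRUE
fam1_og2	fam1	17	0	TRUE
fam1_og2	fam1	19	1	TRUE
fam1_og2	fam1	26	2	FALSE
fam1_og2	fam1	38	2	TRUE
fam1_og2	fam1	51	0	TRUE
fam1_og2	fam1	57	2	TRUE
fam1_og2	fam1	58	0	TRUE
fam1_og2	fam1	59	0	TRUE
fam2_og1	fam2	10	0	TRUE
fam2_og1	fam2	13	2	FALSE
fam2_og1	fam2	14	0	TRUE
fam2_og1	fam2	16	2	TRUE
fam2_og1	fam2	26	1	TRUE
fam2_og1	fam2	38	1	TRUE
fam2_og2	fam2	10	0	TRUE
fam2_og2	fam2	14	0	TRUE
fam2_og2	fam2	16	2	TRUE
fam2_og2	fam2	20	0	TRUE
fam2_og2	fam2	24	1	TRUE
fam2_og2	fam2	25	1	TRUE
fam2_og2	fam2	26	1	TRUE
fam2_og2	fam2	38	1	TRUE
fam2_og2	fam2	48	1	TRUE
fam2_og2	fam2	54	1	TRUE
fam2_og2	fam2	56	0	TRUE
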