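subdataset	n_seq	total_length	max_sens	pvalue	sensitivity
mapping1.adult_mesoderm	34	254800	0.71	0.34	0.14
mapping1.amnioserosa	5	28085	0.76	0.00	0.43
mapping1.blastoderm	7	49635	0.84	0.02	0.15
mapping1.cardiac_mesoderm	77	698840	0.77	0.00	0.26
mapping1.cns	8	42979	0.76	0.94	0.04
mapping1.dorsal_ectoderm	34	352108	0.80	0.55	0.08
mapping1.ectoderm	8	67490	0.77	0.72	0.07
mapping1.endoderm	37	311000	0.72	0.00	0.47
mapping1.eye	51	416473	0.74	0.01	0.31
mapping1.fat_body	16	92723	0.82	0.14	0.21
mapping1.female_gonad	6	49494	0.70	0.59	0.04
mapping1.glia	18	156531	0.69	0.00	0.56
mapping1.imaginal_disc	5	22831	0.93	0.00	0.19
mapping1.male_gonad	10	44269	0.62	0.03	0.24
mapping1.malpighian_tubules	7	63008	0.82	0.24	0.12
mapping1.mesectoderm	47	441597	0.77	0.58	0.05
mapping1.mesoderm	12	149915	0.80	0.05	0.19
mapping1.neuroectoderm	69	616635	0.76	0.02	0.21
mapping1.pns	8	69044	0.85	0.37	0.11
mapping1.salivary_gland	4	31338	0.81	0.27	0.08
mapping1.somatic_muscle	5	45712	0.83	0.29	0.14
mapping1.tracheal_system	16	87140	0.72	0.71	0.05
mapping1.ventral_ectoderm	45	233441	0.75	0.01	0.23
mapping1.visceral_mesoderm	7	40315	0.80	0.04	0.19
mapping2.ectoderm	54	534081	0.78	0.02	0.16
mapping2.eye	24	234532	0.78	0.27	0.12
mapping2.imaginal_disc	21	154400	0.69	0.16	0.10
mapping2.mesoderm	6	47232	0.74	0.62	0.08
mapping2.neuronal	12	86317	0.79	0.49	0.09
mapping2.reproductive_system	9	111351	0.85	0.00	0.30
mapping2.wing	12	84154	0.77	0.02	0.17
mapping3.adult	12	54278	0.77	0.00	0.20
mapping3.larva	33	340094	0.78	0.97	0.03
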