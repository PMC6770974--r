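gene_id	chromosome
GmLac1	chr01
GmLac2	chr01
GmLac3	chr01
GmLac4	chr01
GmLac5	chr01
GmLac6	chr01
GmLac7	chr02
GmLac8	chr02
GmLac9	chr03
GmLac10	chr04
GmLac11	chr04
GmLac12	chr05
GmLac13	chr05
GmLac14	chr05
GmLac15	chr05
GmLac16	chr06
GmLac17	chr06
GmLac18	chr06
GmLac19	chr06
GmLac20	chr06
GmLac21	chr07
GmLac22	chr07
GmLac23	chr07
GmLac24	chr07
GmLac25	chr07
GmLac26	chr07
GmLac27	chr09
GmLac28	chr10
GmLac29	chr10
GmLac30	chr10
GmLac31	chr10
GmLac32	chr10
GmLac33	chr10
GmLac34	chr10
GmLac35	chr11
GmLac36	chr11
GmLac37	chr11
GmLac38	chr11
GmLac39	chr11
GmLac40	chr11
GmLac41	chr12
GmLac42	chr12
GmLac43	chr12
GmLac44	chr12
GmLac45	chr12
GmLac46	chr12
GmLac47	chr12
GmLac48	chr13
GmLac49	chr13
GmLac50	chr13
GmLac51	chr13
GmLac52	chr13
GmLac53	chr13
GmLac54	chr13
GmLac55	chr13
GmLac56	chr14
GmLac57	chr14
GmLac58	chr14
GmLac59	chr14
GmLac60	chr14
GmLac61	chr14
GmLac62	chr14
GmLac63	chr15
GmLac64	chr16
GmLac65	chr17
GmLac66	chr17
GmLac67	chr17
GmLac68	chr17
GmLac69	chr17
GmLac70	chr18
GmLac71	chr18
GmLac72	chr18
GmLac73	chr18
GmLac74	chr18
GmLac75	chr18
GmLac76	chr18
GmLac77	chr18
GmLac78	chr18
GmLac79	chr18
GmLac80	chr18
GmLac81	chr18
GmLac82	chr19
GmLac83	chr19
GmLac84	chr19
GmLac85	chr20
GmLac86	chr20
GmLac87	chr20
GmLac88	chr20
GmLac89	chr20
GmLac90	chr20
GmLac91	scaffold_27
GmLac92	scaffold_27
GmLac93	scaffold_614
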