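probe_id	chrom	pos_mb	cluster	neg_log10_p	gene_symbol	nfold	direction
A_87_P022983	3	104.30	4	4.58	WDR35	7.80	Up
A_87_P021624	3	104.33	4	5.85	LAPTM4A	1.28	Down
A_87_P018137	3	104.80	4	5.23	HS1BP3	2.53	Up
A_87_P254443	3	104.84	4	4.28	LDAH	1.34	Up
A_87_P176188	3	105.39	4	4.16	LOC769627	1.94	Down
A_87_P304288	8	3.73	7	5.64	LOC101751271	1.88	Down
A_87_P052241	8	4.03	7	4.01	MTA1	1.19	Down
A_87_P079496	8	25.66	8	4.58	GLIS1	2.02	Down
A_87_P016336	8	26.00	8	4.10	TTC4	1.37	Down
A_87_P022335	8	26.00	8	4.35	PARS2	1.36	Up
A_87_P139413	9	5.67	9	4.17	AQP12	1.78	Up
A_87_P012759	9	5.67	9	6.92	AQP12	1.67	Up
A_87_P077026	9	5.68	9	4.09	PAK2	1.96	Up
A_87_P280878	9	5.69	9	7.95	PAK2	1.81	Up
A_87_P285338	9	5.76	9	5.38	RNF168	1.27	Down
A_87_P017768	9	5.98	9	4.12	PPP1R7	1.21	Down
A_87_P223178	9	5.98	9	4.05	PPP1R7	1.28	Down
A_87_P023784	9	6.18	9	6.00	ETV5	1.40	Down
A_87_P077621	9	16.69	10	4.17	SLC12A9	1.51	Down
A_87_P005339	9	16.78	10	6.92	CYP2J6L1	2.24	Up
A_87_P177293	9	16.78	10	4.09	CYP2J6L1	1.97	Up
A_87_P077646	9	16.79	10	7.95	CYP2J2L5	2.25	Up
A_87_P181713	19	6.94	12	4.07	FAM101B	2.17	Down
A_87_P017169	19	7.26	12	4.86	PTRH2	1.16	Down
A_87_P011731	19	8.05	12	7.95	CA4	1.74	Down
A_87_P018194	24	25.84	13	4.19	VPS26B	3.85	Up
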