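trait	cluster	chrom	start_bp	end_bp	length_mb	n_sig	n_genome_wide
FPD	1	3	58834628	59725450	0.89	3	0
FPD	2	4	53335653	53945398	0.61	6	0
FPD	3	6	3059760	3075330	0.02	2	0
FPD	4	8	25309634	25399547	0.09	2	0
FPD_meta	1	1	58412953	58831069	0.42	3	0
FPD_meta	2	1	149753999	150465791	0.71	2	0
FPD_meta	3	2	37372218	39828657	2.46	2	0
FPD_meta	4	3	102969523	105470402	2.50	2	0
FPD_meta	5	3	107262448	109945836	2.68	3	0
FPD_meta	6	4	87030671	87082448	0.05	2	0
FPD_meta	7	8	3612454	5410229	1.80	3	0
FPD_meta	8	8	23799410	26002938	2.20	9	3
FPD_meta	9	9	5650341	7645421	2.00	5	2
FPD_meta	10	9	16342044	18770002	2.43	13	3
FPD_meta	11	9	18726350	20815056	2.09	4	0
FPD_meta	12	19	6883105	8064270	1.18	2	0
FPD_meta	13	24	2480724	3900089	1.42	3	0
APD	1	1	64103417	67037983	2.93	3	0
APD	2	1	116041775	117435846	1.39	6	2
APD	3	2	83445347	86114050	2.67	2	0
APD	4	4	33821	552165	0.52	7	0
APD	5	5	56835282	58214037	1.38	6	2
APD	6	18	8135718	10191144	2.06	11	0
APD	7	21	504778	3009557	2.50	7	0
APR	1	7	6241588	6327771	0.09	3	0
APR	2	7	9746560	12631641	2.89	10	0
APR	3	7	13378513	14679901	1.30	5	0
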