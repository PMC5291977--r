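trait	snp_id	chrom	pos_bp	neg_log10_p	gene_freq	fst
APD	Gga_rs14552589	5	57353834	6.8	0.13	NA
APD	GGaluGA290503	5	57401911	6.4	0.13	NA
APD	Gga_rs13923655	1	116041775	6.0	0.44	NA
APD	Gga_rs15388609	1	116062599	5.8	0.44	NA
FPD_meta	GGaluGA341482	9	17128657	7.4	0.45	0.76
FPD_meta	Gga_rs14676055	9	16629471	6.4	0.44	0.80
FPD_meta	GGaluGA341217	9	16764865	6.4	0.44	0.80
FPD_meta	Gga_rs13766455	9	5961337	6.0	0.46	0.82
FPD_meta	Gga_rs16519883	5	59368007	5.9	0.44	0.91
FPD_meta	Gga_rs14667686	9	6739756	5.9	0.48	0.92
FPD_meta	Gga_rs14652254	8	23911149	5.8	0.48	0.97
FPD_meta	Gga_rs15930799	8	23892743	5.8	0.48	0.97
FPD_meta	Gga_rs14652966	8	24679820	5.8	0.41	0.84
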