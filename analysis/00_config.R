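# Shared configuration for the numbered analysis scripts.
#
# The synthetic study mirrors the real design: two divergently selected
# founder lines, a 960-hen F2 cross in four hatches, chip genotypes on
# the nine largest chicken autosomes, three count traits, and a 9-vs-9
# brain expression comparison. 6,000 SNPs (about a fifth of the
# post-QC chip density) keep a full desktop run in the minutes range;
# every stage scales linearly in SNP count.

library(peckscan)

out_dir <- file.path("results", "analysis")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

study_cfg <- sim_config(
  n_snps = 6000,
  chrom_lengths = c(`1` = 196e6, `2` = 149e6, `3` = 111e6, `4` = 91e6,
                    `5` = 60e6, `6` = 36e6, `7` = 38e6, `8` = 30e6,
                    `9` = 24e6),
  founder_divergence = 0.05,       # closely related lines -> high resolution
  n_qtl = 6, qtl_add = 0.08, qtl_dom = 0.02,
  qtl_freq_shift = 0.95,           # selected loci strongly diverged
  baseline_log_rate = log(5),
  expression = list(n_probes = 4000, cis_fraction = 0.25,
                    cis_effect_sd = 0.8, noise_sd = 0.3),
  seed = 20170203)

thresholds <- list(sig = 5e-5, weak = 5e-4, gw = 0.05)
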