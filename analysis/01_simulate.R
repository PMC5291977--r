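#!/usr/bin/env Rscript
# Stage 1 — simulate the study: founder-line allele frequencies under
# divergent selection, the reciprocal F2 cross with recombination, and
# Poisson count phenotypes. Writes PLINK text PED/MAP, the phenotype
# table, and the QTL truth so later stages run from files alone.

source(file.path("analysis", "00_config.R"))

freqs <- simulate_founder_lines(study_cfg)
message(sprintf("simulated %d SNPs on %d chromosomes; %d QTL planted",
                nrow(freqs), length(unique(freqs$chrom)), sum(freqs$is_qtl)))

cross <- simulate_f2_cross(study_cfg, freqs)
cross <- simulate_count_phenotypes(study_cfg, cross)
ds <- orient_minor(cross$dataset)
message(sprintf("F2: %d hens, %d F1 sires, mean FPD count %.2f",
                n_individuals(ds), length(unique(ds$ped$sire)),
                mean(ds$pheno$FPD)))

write_ped_map(ds, file.path(out_dir, "f2"))
write_phenotypes(ds, file.path(out_dir, "phenotypes.tsv"))

# founder panel for the selection-signature stand-in scan
panel <- simulate_founder_panel(study_cfg, freqs, n_per_line = 30)
write_ped_map(panel, file.path(out_dir, "founder_panel"))

utils::write.table(cross$truth, file.path(out_dir, "qtl_truth.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("stage 1 outputs under ", out_dir)
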