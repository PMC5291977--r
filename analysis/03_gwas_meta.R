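#!/usr/bin/env Rscript
# Stage 3 — single-marker Poisson GWAS for FPD, APD and APR with fixed
# hatch, sire and dam effects; permutation F_ST selection-signature
# p-values from the founder panel; Fisher's combined-probability
# meta-analysis for FPD (the FPD_meta trait).

source(file.path("analysis", "00_config.R"))

ds <- read_genotypes(file.path(out_dir, "f2.ped"))
ds <- attach_phenotypes(ds, read_phenotypes(file.path(out_dir,
                                                      "phenotypes.tsv")))
ds <- filter_variants(ds)$dataset

for (trait in c("FPD", "APD", "APR")) {
  res <- snp_association(ds, trait)
  n_sig <- sum(res$p_nominal <= thresholds$sig, na.rm = TRUE)
  n_gw <- sum(res$p_genome_wide <= thresholds$gw, na.rm = TRUE)
  fdr <- if (n_sig > 0)
    max(res$q_value[res$p_nominal <= thresholds$sig], na.rm = TRUE) else NA
  message(sprintf(
    "%s: %d tested, %d significant at %g (%d genome-wide), FDR among hits %.3g",
    trait, sum(!is.na(res$p_nominal)), n_sig, thresholds$sig, n_gw, fdr))
  utils::write.table(res, file.path(out_dir, sprintf("assoc_%s.tsv", trait)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manh <- data.frame(chrom = res$chrom, pos_bp = res$pos_bp,
                     neg_log10_p = -log10(pmax(res$p_nominal, 1e-300)))
  utils::write.table(manh,
                     file.path(out_dir, sprintf("manhattan_%s.tsv", trait)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

panel <- read_genotypes(file.path(out_dir, "founder_panel.ped"))
panel$ped$line <- substr(panel$ped$id, 1, 3)
sel <- selection_pvalues(panel, n_perm = 2000, seed = study_cfg$seed + 6L)
utils::write.table(sel, file.path(out_dir, "selection_pvalues.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

fpd <- utils::read.table(file.path(out_dir, "assoc_FPD.tsv"), header = TRUE,
                         sep = "\t", stringsAsFactors = FALSE,
                         colClasses = c(chrom = "character"))
meta <- run_meta(fpd, sel)
message(sprintf("FPD_meta: %d significant at %g (FPD alone: %d)",
                sum(meta$p_meta <= thresholds$sig, na.rm = TRUE),
                thresholds$sig,
                sum(meta$p_nominal <= thresholds$sig, na.rm = TRUE)))
utils::write.table(meta, file.path(out_dir, "assoc_FPD_meta.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
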