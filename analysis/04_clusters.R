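#!/usr/bin/env Rscript
# Stage 4 — build trait-associated SNP clusters (chained significant
# SNPs, weak-SNP bounds), count genome-wide significant members, check
# cross-trait overlap, and compare clusters against the planted QTL.

source(file.path("analysis", "00_config.R"))

read_assoc <- function(name)
  utils::read.table(file.path(out_dir, sprintf("assoc_%s.tsv", name)),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = c(chrom = "character"))

clusters <- list()
for (trait in c("FPD", "APD", "APR")) {
  res <- read_assoc(trait)
  clusters[[trait]] <- build_clusters(
    res, p_col = "p_nominal", sig = thresholds$sig, weak = thresholds$weak,
    trait = trait, gw_col = "p_genome_wide", gw_threshold = thresholds$gw)
}
meta <- read_assoc("FPD_meta")
clusters$FPD_meta <- build_clusters(
  meta, p_col = "p_meta", sig = thresholds$sig, weak = thresholds$weak,
  trait = "FPD_meta", gw_col = "p_meta_genome_wide",
  gw_threshold = thresholds$gw)

for (nm in names(clusters)) {
  cl <- clusters[[nm]]
  message(sprintf("%s: %d cluster(s), total span %.2f Mb", nm, nrow(cl),
                  sum(cl$length_mb)))
  utils::write.table(as.data.frame(cl),
                     file.path(out_dir, sprintf("clusters_%s.tsv", nm)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

ov <- overlap_clusters(clusters$FPD, clusters$FPD_meta)
message(sprintf("FPD vs FPD_meta overlapping cluster pairs: %d", nrow(ov)))

truth <- utils::read.table(file.path(out_dir, "qtl_truth.tsv"),
                           header = TRUE, sep = "\t",
                           colClasses = c(chrom = "character"))
hits <- snps_in_clusters(truth, clusters$FPD_meta)
message(sprintf("planted QTL inside FPD_meta clusters: %d of %d",
                hits$n_inside, nrow(truth)))
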