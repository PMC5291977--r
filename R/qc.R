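#' Minor allele frequency of a dosage vector
#'
#' `sum(dosages) / (2 * n_nonmissing)`, folded to `<= 0.5`. Missing
#' dosages are excluded from numerator and denominator.
#'
#' @param dosages vector of 0/1/2/NA.
#' @return frequency in `[0, 0.5]`, or `NA` when every dosage is
#'   missing.
#' @export
compute_maf <- function(dosages) {
  ok <- !is.na(dosages)
  if (!any(ok)) return(NA_real_)
  f <- sum(dosages[ok]) / (2 * sum(ok))
  min(f, 1 - f)
}

#' Vectorised per-SNP MAF
#' @param dataset a `peck_dataset`.
#' @return named vector of folded frequencies (`NA` where all dosages
#'   are missing).
#' @export
maf_by_snp <- function(dataset) {
  n_ok <- colSums(!is.na(dataset$geno))
  f <- colSums(dataset$geno, na.rm = TRUE) / (2 * n_ok)
  f[n_ok == 0] <- NA_real_
  pmin(f, 1 - f)
}

#' Per-SNP call frequency
#' @param dataset a `peck_dataset`.
#' @return named vector, fraction of individuals with a non-missing
#'   dosage per SNP.
#' @export
call_frequency <- function(dataset) colMeans(!is.na(dataset$geno))

#' Chromosomes excluded from the scan
#'
#' Sex chromosomes, the two unplaced linkage groups of the chicken
#' assembly, and the label used for unassigned SNPs.
#' @export
peck_excluded_chroms <- c("W", "Z", "LGE22C19W28_E50C23", "LGE64",
                          "unassigned")

#' Apply the SNP filtering rules
#'
#' Removes SNPs, in a fixed attribution order, by: (1) excluded or
#' unassigned chromosome; (2) call frequency strictly below
#' `callrate_min`; (3) MAF strictly below `maf_min`. A SNP removed by
#' an earlier rule is not re-counted by a later one, so the report
#' reconciles exactly. Boundary values are kept (the rules are strict
#' "lower than" comparisons). The retained set preserves input order,
#' and filtering is idempotent.
#'
#' @param dataset a `peck_dataset`.
#' @param maf_min minimum minor allele frequency (default 0.03).
#' @param callrate_min minimum call frequency (default 0.95).
#' @param excluded_chroms chromosome labels to drop; SNPs with `NA` or
#'   empty labels count as unassigned.
#' @return list with `dataset` (filtered) and `report` (a `peck_qc`
#'   object: counts and per-rule SNP id lists).
#' @export
filter_variants <- function(dataset, maf_min = 0.03, callrate_min = 0.95,
                            excluded_chroms = peck_excluded_chroms) {
  stopifnot(maf_min >= 0, maf_min <= 1, callrate_min >= 0, callrate_min <= 1)
  map <- dataset$map
  by_chrom <- map$chrom %in% excluded_chroms | is.na(map$chrom) |
    map$chrom == ""
  cr <- call_frequency(dataset)
  by_call <- !by_chrom & cr < callrate_min
  maf <- maf_by_snp(dataset)
  by_maf <- !by_chrom & !by_call & (is.na(maf) | maf < maf_min)
  keep <- !(by_chrom | by_call | by_maf)

  report <- structure(list(
    n_input = nrow(map),
    n_removed = c(chromosome = sum(by_chrom), call_rate = sum(by_call),
                  maf = sum(by_maf)),
    n_retained = sum(keep),
    removed = list(chromosome = map$snp_id[by_chrom],
                   call_rate = map$snp_id[by_call],
                   maf = map$snp_id[by_maf])), class = "peck_qc")

  out <- dataset
  out$map <- map[keep, , drop = FALSE]
  rownames(out$map) <- NULL
  out$geno <- dataset$geno[, keep, drop = FALSE]
  list(dataset = out, report = report)
}

#' @export
print.peck_qc <- function(x, ...) {
  cat(sprintf("SNP QC: %d in, %d retained\n", x$n_input, x$n_retained))
  for (r in names(x$n_removed))
    cat(sprintf("  removed by %-10s %d\n", r, x$n_removed[[r]]))
  invisible(x)
}

#' Write a QC report as TSV + JSON
#' @param report a `peck_qc` object.
#' @param prefix output prefix; writes `<prefix>.tsv` (per-rule SNP
#'   lists) and `<prefix>.json` (counts).
#' @return prefix, invisibly.
#' @export
write_qc_report <- function(report, prefix) {
  rows <- do.call(rbind, lapply(names(report$removed), function(r)
    if (length(report$removed[[r]]))
      data.frame(rule = r, snp_id = report$removed[[r]])))
  if (is.null(rows)) rows <- data.frame(rule = character(), snp_id = character())
  utils::write.table(rows, paste0(prefix, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(n_input = report$n_input,
                            n_removed = as.list(report$n_removed),
                            n_retained = report$n_retained),
                       paste0(prefix, ".json"), auto_unbox = TRUE)
  invisible(prefix)
}
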