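#' Construct a genotype dataset
#'
#' The central container of the pipeline: an ordered SNP map, a dosage
#' matrix (individual x SNP, values 0/1/2/NA counting copies of one
#' allele), a pedigree/covariate table and optionally a phenotype table.
#'
#' @param map data.frame with `snp_id`, `chrom`, `pos_bp` (1-based).
#' @param geno integer matrix, rows = individuals, columns = SNPs in map
#'   order; values in \{0, 1, 2, NA\}.
#' @param ped data.frame with `id`, `sire`, `dam`, `hatch`, `line`
#'   (`"0"` in sire/dam flags a founder).
#' @param pheno optional data.frame with `id`, trait counts and
#'   `observed_minutes`.
#' @return object of class `peck_dataset`.
#' @export
new_peck_dataset <- function(map, geno, ped, pheno = NULL) {
  stopifnot(all(c("snp_id", "chrom", "pos_bp") %in% names(map)),
            ncol(geno) == nrow(map), nrow(geno) == nrow(ped),
            all(c("id", "sire", "dam") %in% names(ped)))
  if (anyDuplicated(map$snp_id)) stop("duplicate snp_id in map")
  if (any(map$pos_bp < 1)) stop("pos_bp must be >= 1")
  ord <- order(match(map$chrom, unique(map$chrom)), map$pos_bp)
  map <- map[ord, , drop = FALSE]
  geno <- geno[, ord, drop = FALSE]
  rownames(map) <- NULL
  colnames(geno) <- map$snp_id
  if (any(geno < 0 | geno > 2 | geno != as.integer(geno), na.rm = TRUE))
    stop("dosages must be 0, 1, 2 or NA")
  structure(list(map = map, geno = geno, ped = ped, pheno = pheno),
            class = "peck_dataset")
}

#' @export
print.peck_dataset <- function(x, ...) {
  cat(sprintf("peck_dataset: %d individuals x %d SNPs on %d chromosome(s)\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$map$chrom))))
  if (!is.null(x$pheno))
    cat("phenotypes:", paste(setdiff(names(x$pheno),
                                     c("id", "observed_minutes")),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Number of individuals / SNPs
#' @param x a `peck_dataset`.
#' @return integer count.
#' @export
n_individuals <- function(x) nrow(x$geno)

#' @rdname n_individuals
#' @export
n_snps <- function(x) ncol(x$geno)

#' Orient dosages to count the minor allele
#'
#' Columns whose counted-allele frequency exceeds 0.5 are flipped
#' (dosage -> 2 - dosage). Ties at exactly 0.5 are left as stored; the
#' PED reader resolves them by counting the alphabetically smaller
#' allele.
#'
#' @param dataset a `peck_dataset`.
#' @return the dataset with all in-sample counted-allele frequencies
#'   <= 0.5.
#' @export
orient_minor <- function(dataset) {
  f <- colMeans(dataset$geno, na.rm = TRUE) / 2
  flip <- which(!is.na(f) & f > 0.5)
  if (length(flip)) dataset$geno[, flip] <- 2L - dataset$geno[, flip]
  dataset
}
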