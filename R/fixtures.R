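#' Bundled worked-example tables
#'
#' Small reference tables from the published divergent-line
#' feather-pecking F2 study the pipeline emulates, shipped as plain TSV
#' for worked examples and regression tests:
#'
#' * `reported_snps()` — the genome-wide significant SNPs for the APD
#'   trait and the FPD meta-analysis, with chromosome, bp position
#'   (galGal2.1), `-log10 p`, F2 gene frequency and founder-line F_ST.
#' * `reported_clusters()` — the association clusters for FPD,
#'   FPD_meta, APD and APR: bounds, printed length in Mb, and counts of
#'   significant and genome-wide significant member SNPs.
#' * `reported_de_probes()` — the 26 differentially expressed
#'   microarray probes located in FPD_meta clusters, with printed
#'   `-log10 p`, gene symbol, fold change and direction.
#'
#' Values are stored verbatim as printed; in particular the
#' `neg_log10_p` column of the DE table is not asserted to follow any
#' particular correction convention.
#'
#' @param trait optional trait filter.
#' @return data.frame.
#' @export
reported_snps <- function(trait = NULL) {
  d <- utils::read.table(
    system.file("extdata", "reported_significant_snps.tsv",
                package = "peckscan"),
    header = TRUE, sep = "\t", stringsAsFactors = FALSE,
    colClasses = c("character", "character", "character", "integer",
                   "numeric", "numeric", "numeric"))
  if (!is.null(trait)) d <- d[d$trait %in% trait, , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' @rdname reported_snps
#' @export
reported_clusters <- function(trait = NULL) {
  d <- utils::read.table(
    system.file("extdata", "reported_clusters.tsv", package = "peckscan"),
    header = TRUE, sep = "\t", stringsAsFactors = FALSE,
    colClasses = c("character", "integer", "character", "numeric",
                   "numeric", "numeric", "integer", "integer"))
  if (!is.null(trait)) d <- d[d$trait %in% trait, , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' @rdname reported_snps
#' @export
reported_de_probes <- function() {
  utils::read.table(
    system.file("extdata", "reported_de_probes.tsv", package = "peckscan"),
    header = TRUE, sep = "\t", stringsAsFactors = FALSE,
    colClasses = c("character", "character", "numeric", "integer",
                   "numeric", "character", "numeric", "character"))
}
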