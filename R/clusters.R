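#' Build trait-associated SNP clusters
#'
#' Per chromosome, significant SNPs (`p <= sig`) are chained: each
#' consecutive pair at most `link_mb` apart joins one chain, and chains
#' with at least two SNPs seed a cluster. The cluster midpoint is the
#' centre of the seed's significant positions, and the bounds are the
#' outermost weakly significant SNPs (`p <= weak`; significant SNPs
#' qualify, the thresholds being nested) within `flank_mb` of the
#' midpoint on each side. If a seed SNP falls outside the flank window
#' (possible for long chains) a warning is emitted and the bounds are
#' truncated to the window. Clusters are numbered per trait in
#' (chromosome, start) order of the input.
#'
#' @param results data.frame with `snp_id`, `chrom`, `pos_bp` and a
#'   p-value column, sorted by (chrom, pos_bp); an unsorted input is an
#'   error.
#' @param p_col name of the p-value column (e.g. `"p_nominal"` or
#'   `"p_meta"`).
#' @param sig significant threshold (default 5e-5).
#' @param weak weakly-significant threshold (default 5e-4); must be
#'   >= `sig`.
#' @param link_mb maximum distance between consecutive significant
#'   SNPs in a chain (default 3 Mb).
#' @param flank_mb half-width of the bound search window around the
#'   midpoint (default 1.5 Mb).
#' @param trait label stored in the output.
#' @param gw_col optional column with genome-wide corrected p-values,
#'   used for the `n_genome_wide` member count (at `gw_threshold`).
#' @param gw_threshold genome-wide significance level (default 0.05).
#' @return data.frame of class `peck_clusters`: `trait`, `cluster`,
#'   `chrom`, `start_bp`, `end_bp`, `length_mb`, `midpoint_bp`,
#'   `n_sig`, `n_weak`, `n_genome_wide`, `sig_snps` (comma-joined ids).
#' @export
build_clusters <- function(results, p_col = "p_nominal",
                           sig = 5e-5, weak = 5e-4,
                           link_mb = 3, flank_mb = 1.5,
                           trait = if ("trait" %in% names(results))
                             results$trait[1] else NA_character_,
                           gw_col = NULL, gw_threshold = 0.05) {
  stopifnot(sig <= weak, p_col %in% names(results))
  ord <- order(match(results$chrom, unique(results$chrom)), results$pos_bp)
  if (!identical(ord, seq_len(nrow(results))))
    stop("results must be sorted by (chrom, pos_bp)")
  p <- results[[p_col]]
  link_bp <- link_mb * 1e6; flank_bp <- flank_mb * 1e6
  rows <- list()
  for (ch in unique(results$chrom)) {
    on <- which(results$chrom == ch)
    sig_i <- on[!is.na(p[on]) & p[on] <= sig]
    if (length(sig_i) < 2) next
    pos_sig <- results$pos_bp[sig_i]
    chain <- cumsum(c(0, diff(pos_sig) > link_bp))
    for (cid in unique(chain)) {
      members <- sig_i[chain == cid]
      if (length(members) < 2) next
      mpos <- results$pos_bp[members]
      mid <- (min(mpos) + max(mpos)) / 2
      lo <- mid - flank_bp; hi <- mid + flank_bp
      if (any(mpos < lo | mpos > hi))
        warning(sprintf(
          "cluster seed on %s spans beyond +-%g Mb of its midpoint; bounds truncated",
          ch, flank_mb))
      weak_i <- on[!is.na(p[on]) & p[on] <= weak &
                     results$pos_bp[on] >= lo & results$pos_bp[on] <= hi]
      start <- min(results$pos_bp[weak_i]); end <- max(results$pos_bp[weak_i])
      inside <- on[results$pos_bp[on] >= start & results$pos_bp[on] <= end]
      n_gw <- if (!is.null(gw_col))
        sum(results[[gw_col]][inside] <= gw_threshold, na.rm = TRUE)
      else NA_integer_
      rows[[length(rows) + 1L]] <- data.frame(
        trait = trait, cluster = NA_integer_, chrom = ch,
        start_bp = start, end_bp = end,
        length_mb = cluster_length_mb(start, end), midpoint_bp = mid,
        n_sig = sum(!is.na(p[inside]) & p[inside] <= sig),
        n_weak = sum(!is.na(p[inside]) & p[inside] <= weak),
        n_genome_wide = n_gw,
        sig_snps = paste(results$snp_id[intersect(inside, sig_i)],
                         collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(trait = character(), cluster = integer(),
                  chrom = character(), start_bp = numeric(),
                  end_bp = numeric(), length_mb = numeric(),
                  midpoint_bp = numeric(), n_sig = integer(),
                  n_weak = integer(), n_genome_wide = integer(),
                  sig_snps = character(), stringsAsFactors = FALSE)
  out$cluster <- seq_len(nrow(out))
  class(out) <- c("peck_clusters", "data.frame")
  out
}

#' Cluster length in Mb
#'
#' `(end_bp - start_bp) / 1e6`, rounded half-up to two decimals (the
#' reporting convention of the cluster tables; base `round()` would
#' round half to even).
#'
#' @param start_bp,end_bp cluster bounds (1-based SNP positions).
#' @return length in Mb with two decimals.
#' @export
cluster_length_mb <- function(start_bp, end_bp) {
  stopifnot(all(end_bp >= start_bp))
  floor((end_bp - start_bp) / 1e6 * 100 + 0.5) / 100
}

#' Count SNPs inside clusters
#'
#' A SNP lies in a cluster iff it is on the same chromosome and
#' `start_bp <= pos <= end_bp` (both bounds inclusive — the bounds are
#' themselves SNP positions).
#'
#' @param snp_positions data.frame with `snp_id` (optional), `chrom`,
#'   `pos_bp`.
#' @param clusters a `peck_clusters` data.frame (or any frame with
#'   `cluster`, `chrom`, `start_bp`, `end_bp`).
#' @return list with `assignments` (one row per SNP x containing
#'   cluster), `per_cluster` (named counts) and `n_inside` (number of
#'   distinct SNPs inside at least one cluster).
#' @export
snps_in_clusters <- function(snp_positions, clusters) {
  hits <- list()
  for (i in seq_len(nrow(clusters))) {
    sel <- which(snp_positions$chrom == clusters$chrom[i] &
                   snp_positions$pos_bp >= clusters$start_bp[i] &
                   snp_positions$pos_bp <= clusters$end_bp[i])
    if (length(sel))
      hits[[length(hits) + 1L]] <- data.frame(
        snp = sel,
        snp_id = if ("snp_id" %in% names(snp_positions))
          snp_positions$snp_id[sel] else as.character(sel),
        cluster = clusters$cluster[i],
        stringsAsFactors = FALSE)
  }
  assignments <- if (length(hits)) do.call(rbind, hits)
  else data.frame(snp = integer(), snp_id = character(),
                  cluster = integer(), stringsAsFactors = FALSE)
  per_cluster <- table(factor(assignments$cluster,
                              levels = clusters$cluster))
  list(assignments = assignments,
       per_cluster = per_cluster,
       n_inside = length(unique(assignments$snp)))
}

#' Overlapping cluster pairs between two sets
#'
#' Pairs on the same chromosome whose `[start_bp, end_bp]` intervals
#' intersect.
#'
#' @param clusters_a,clusters_b `peck_clusters` data.frames.
#' @return data.frame `cluster_a`, `cluster_b`, `chrom`,
#'   `overlap_start`, `overlap_end`.
#' @export
overlap_clusters <- function(clusters_a, clusters_b) {
  out <- list()
  for (i in seq_len(nrow(clusters_a))) for (j in seq_len(nrow(clusters_b))) {
    if (clusters_a$chrom[i] != clusters_b$chrom[j]) next
    lo <- max(clusters_a$start_bp[i], clusters_b$start_bp[j])
    hi <- min(clusters_a$end_bp[i], clusters_b$end_bp[j])
    if (lo <= hi)
      out[[length(out) + 1L]] <- data.frame(
        cluster_a = clusters_a$cluster[i], cluster_b = clusters_b$cluster[j],
        chrom = clusters_a$chrom[i], overlap_start = lo, overlap_end = hi,
        stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(cluster_a = integer(), cluster_b = integer(),
                  chrom = character(), overlap_start = numeric(),
                  overlap_end = numeric(), stringsAsFactors = FALSE)
}
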