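#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom
#' and a two-sided p-value. Degenerate inputs are defined rather than
#' raised: with both variances zero and equal means, `t = 0, p = 1`;
#' with both variances zero and different means the p-value collapses
#' to 0 and the result is flagged `degenerate`.
#'
#' @param x,y numeric vectors with at least two values each.
#' @return list `t`, `df`, `p` (+ `degenerate` flag).
#' @export
welch_t_test <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("need >= 2 values per group")
  vx <- stats::var(x); vy <- stats::var(y)
  dm <- mean(x) - mean(y)
  if (vx == 0 && vy == 0) {
    if (dm == 0) return(list(t = 0, df = nx + ny - 2, p = 1,
                             degenerate = FALSE))
    return(list(t = sign(dm) * Inf, df = nx + ny - 2, p = 0,
                degenerate = TRUE))
  }
  se2 <- vx / nx + vy / ny
  t <- dm / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), degenerate = FALSE)
}

#' Fold change between line means on the log2 scale
#'
#' `nfold = 2^|mean_H - mean_L| >= 1`; direction is `Up` when the HFP
#' mean exceeds the LFP mean, `Down` otherwise. A zero difference is
#' reported as `Up` with `zero_diff = TRUE`.
#'
#' @param mean_log2_h,mean_log2_l finite line means (log2 scale).
#' @return list `nfold`, `direction`, `zero_diff`.
#' @export
fold_change <- function(mean_log2_h, mean_log2_l) {
  stopifnot(is.finite(mean_log2_h), is.finite(mean_log2_l))
  d <- mean_log2_h - mean_log2_l
  list(nfold = 2^abs(d),
       direction = if (d >= 0) "Up" else "Down",
       zero_diff = d == 0)
}

#' Assign probes to clusters by genomic position
#'
#' Probe interval coordinates (BED-like, 0-based half-open) are reduced
#' to a 1-based midpoint; a probe belongs to the cluster whose
#' `[start_bp, end_bp]` interval contains that point (bounds
#' inclusive). A probe hit by several clusters (possible across
#' traits) is assigned to the first by (chrom, start) with a warning.
#'
#' @param probes data.frame with `probe_id`, `chrom` and either
#'   `pos_bp` (1-based point) or `start`/`end` (BED convention).
#' @param clusters a `peck_clusters` data.frame.
#' @return `probes` with columns `pos_bp` and `cluster` (`NA` =
#'   unassigned); `attr(, "m")` is the number of assigned probes, the
#'   Bonferroni test count.
#' @export
map_probes_to_clusters <- function(probes, clusters) {
  if (!"pos_bp" %in% names(probes)) {
    stopifnot(all(c("start", "end") %in% names(probes)))
    probes$pos_bp <- probes$start + (probes$end - probes$start) %/% 2 + 1L
  }
  cl <- clusters[order(match(clusters$chrom, unique(clusters$chrom)),
                       clusters$start_bp), , drop = FALSE]
  probes$cluster <- NA_integer_
  multi <- 0L
  for (i in seq_len(nrow(cl))) {
    hit <- probes$chrom == cl$chrom[i] &
      probes$pos_bp >= cl$start_bp[i] & probes$pos_bp <= cl$end_bp[i]
    multi <- multi + sum(hit & !is.na(probes$cluster))
    probes$cluster[hit & is.na(probes$cluster)] <- cl$cluster[i]
  }
  if (multi > 0)
    warning(multi, " probe assignment(s) hit several clusters; first by (chrom, start) kept")
  attr(probes, "m") <- sum(!is.na(probes$cluster))
  probes
}

#' Cluster-restricted differential expression between lines
#'
#' Welch-tests every probe assigned to a cluster (HFP vs LFP
#' replicates), computes fold changes, and Bonferroni-corrects over the
#' number of in-cluster probes only — the multiple-testing burden is
#' deliberately restricted to the association clusters.
#'
#' @param line_h,line_l probe x sample log2 matrices with identical row
#'   names.
#' @param probes probe map with cluster assignments from
#'   [map_probes_to_clusters()].
#' @param all_probes test every probe (for genome-wide background
#'   p-values) instead of in-cluster probes only.
#' @return data.frame: `probe_id`, `chrom`, `pos_bp`, `cluster`,
#'   `t_stat`, `df_welch`, `p_nominal`, `p_bonf`, `neg_log10_p`,
#'   `nfold`, `direction`; `attr(, "m")` is the Bonferroni m.
#' @export
expression_de <- function(line_h, line_l, probes, all_probes = FALSE) {
  stopifnot(identical(rownames(line_h), rownames(line_l)),
            "cluster" %in% names(probes))
  keep <- if (all_probes) seq_len(nrow(probes))
  else which(!is.na(probes$cluster))
  m <- sum(!is.na(probes$cluster))
  rows <- lapply(keep, function(i) {
    id <- probes$probe_id[i]
    x <- line_h[id, ]; y <- line_l[id, ]
    wt <- welch_t_test(x, y)
    fc <- fold_change(mean(x), mean(y))
    data.frame(probe_id = id, chrom = probes$chrom[i],
               pos_bp = probes$pos_bp[i], cluster = probes$cluster[i],
               t_stat = wt$t, df_welch = wt$df, p_nominal = wt$p,
               p_bonf = min(1, m * wt$p),
               neg_log10_p = -log10(max(wt$p, 1e-300)),
               nfold = fc$nfold, direction = fc$direction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "m") <- m
  out
}

#' Enrichment of differentially expressed probes in clusters
#'
#' For each corrected-p threshold, the fraction of significant probes
#' at the genome level, within each chromosome harbouring clusters,
#' and within each cluster — the comparison that diagnoses cis-acting
#' regulatory variation under association clusters. Fractions are
#' monotone non-increasing as the threshold tightens.
#'
#' @param probe_results data.frame with `chrom`, `cluster` and a
#'   corrected p-value column covering the whole background set.
#' @param p_col corrected p-value column name (default `"p_bonf"`).
#' @param thresholds significance cutoffs (default 0.1, 0.05, 0.01).
#' @return data.frame `stratum_type` (genome / chromosome / cluster),
#'   `stratum`, `threshold`, `n`, `n_sig`, `fraction` (`NA` for empty
#'   strata).
#' @export
enrichment_profile <- function(probe_results, p_col = "p_bonf",
                               thresholds = c(0.1, 0.05, 0.01)) {
  stopifnot(p_col %in% names(probe_results))
  p <- probe_results[[p_col]]
  stopifnot(!anyNA(p))
  strata <- list(list(type = "genome", name = "genome",
                      sel = seq_along(p)))
  cl_chroms <- unique(probe_results$chrom[!is.na(probe_results$cluster)])
  for (ch in cl_chroms)
    strata <- c(strata, list(list(type = "chromosome", name = ch,
                                  sel = which(probe_results$chrom == ch))))
  for (cl in sort(unique(probe_results$cluster[!is.na(probe_results$cluster)])))
    strata <- c(strata, list(list(
      type = "cluster", name = as.character(cl),
      sel = which(!is.na(probe_results$cluster) &
                    probe_results$cluster == cl))))
  out <- do.call(rbind, lapply(strata, function(s)
    do.call(rbind, lapply(thresholds, function(th) data.frame(
      stratum_type = s$type, stratum = s$name, threshold = th,
      n = length(s$sel), n_sig = sum(p[s$sel] <= th),
      fraction = if (length(s$sel)) mean(p[s$sel] <= th) else NA_real_,
      stringsAsFactors = FALSE)))))
  rownames(out) <- NULL
  out
}
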