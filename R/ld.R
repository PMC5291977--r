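#' EM estimate of two-locus haplotype frequencies
#'
#' From unphased diploid dosages at two loci, estimates the four
#' haplotype frequencies by expectation-maximisation over the
#' double-heterozygote phase ambiguity. With no double heterozygotes
#' the estimate equals direct haplotype counting exactly.
#'
#' @param dosages_a,dosages_b dosage vectors (0/1/2/NA) for the two
#'   loci over the same individuals.
#' @param tol convergence tolerance on the largest frequency change.
#' @param max_iter iteration cap.
#' @return named vector `c(p11, p10, p01, p00)`: frequencies of the
#'   haplotypes carrying (counted, counted), (counted, other), ...;
#'   non-negative, summing to 1. `NA`s (all four) when fewer than two
#'   individuals are complete at both loci.
#' @export
em_haplotype_frequencies <- function(dosages_a, dosages_b,
                                     tol = 1e-10, max_iter = 1000L) {
  ok <- !is.na(dosages_a) & !is.na(dosages_b)
  a <- dosages_a[ok]; b <- dosages_b[ok]
  n <- length(a)
  if (n < 2) return(c(p11 = NA_real_, p10 = NA_real_,
                      p01 = NA_real_, p00 = NA_real_))
  # 3x3 genotype table; cell [2,2] (double het) is phase-ambiguous
  tab <- table(factor(a, 0:2), factor(b, 0:2))
  # known haplotype counts contributed by the 8 unambiguous cells:
  # h11, h10, h01, h00 count haplotypes (allele at a, allele at b),
  # "1" = counted allele
  base <- c(
    h11 = 2 * tab[3, 3] + tab[3, 2] + tab[2, 3],
    h10 = 2 * tab[3, 1] + tab[3, 2] + tab[2, 1],
    h01 = 2 * tab[1, 3] + tab[1, 2] + tab[2, 3],
    h00 = 2 * tab[1, 1] + tab[1, 2] + tab[2, 1])
  ndh <- tab[2, 2]
  p <- rep(0.25, 4)
  for (it in seq_len(max_iter)) {
    denom <- p[1] * p[4] + p[2] * p[3]
    w <- if (denom > 0) p[1] * p[4] / denom else 0.5
    cnt <- base + ndh * c(w, 1 - w, 1 - w, w)
    pn <- cnt / sum(cnt)
    if (max(abs(pn - p)) < tol) { p <- pn; break }
    p <- pn
  }
  stats::setNames(p, c("p11", "p10", "p01", "p00"))
}

#' r-squared from two-locus haplotype frequencies
#'
#' `r2 = D^2 / (pA qA pB qB)` with `D = p11 - pA * pB`. When either
#' locus is monomorphic the correlation is undefined; 0 is returned
#' with attribute `monomorphic = TRUE`.
#'
#' @param freqs haplotype frequency vector as returned by
#'   [em_haplotype_frequencies()].
#' @return r2 in `[0, 1]`.
#' @export
r2_from_haplotypes <- function(freqs) {
  stopifnot(length(freqs) == 4, all(freqs >= -1e-12),
            abs(sum(freqs) - 1) < 1e-6)
  pa <- freqs[1] + freqs[2]
  pb <- freqs[1] + freqs[3]
  den <- pa * (1 - pa) * pb * (1 - pb)
  if (den <= 0) return(structure(0, monomorphic = TRUE))
  d <- freqs[[1]] - pa * pb
  unname(min(1, d^2 / den))
}

#' Default LD-profile distance bin edges (Mb), half-open (low, high]
#' @export
peck_ld_bins_mb <- c(0, 0.025, 0.05, 0.075, 0.12, 0.2, 0.5, 1.5, 3, 5)

#' Distance-binned LD-decay profile
#'
#' For every same-chromosome SNP pair within `max_dist_bp` on the
#' requested chromosomes, estimates r2 (EM haplotype frequencies), then
#' summarises the r2 distribution per inter-SNP distance bin as the
#' proportion of pairs in each r2 stratum. Pairs where either locus is
#' monomorphic are skipped (the correlation is undefined), not counted
#' as zero.
#'
#' @param dataset a QC'd `peck_dataset`.
#' @param chroms chromosome labels to profile (default the first nine
#'   chicken autosomes).
#' @param max_dist_bp maximum inter-SNP distance (default 5 Mb).
#' @param dist_bins_mb distance bin edges in Mb, half-open (low, high].
#' @param r2_breaks r2 stratum edges.
#' @return list with `pairs` (chrom, snp_a, snp_b, dist_bp, r2) and
#'   `profile` (bin, stratum, n, proportion, mean_r2).
#' @export
ld_decay_profile <- function(dataset, chroms = as.character(1:9),
                             max_dist_bp = 5e6,
                             dist_bins_mb = peck_ld_bins_mb,
                             r2_breaks = c(0, 0.2, 0.4, 0.6, 0.8, 1)) {
  map <- dataset$map
  out <- list()
  for (ch in intersect(chroms, unique(map$chrom))) {
    idx <- which(map$chrom == ch)
    if (length(idx) < 2) next
    pos <- map$pos_bp[idx]
    for (i in seq_len(length(idx) - 1)) {
      j <- idx[(i + 1):length(idx)]
      j <- j[map$pos_bp[j] - pos[i] <= max_dist_bp]
      if (!length(j)) next
      r2 <- vapply(j, function(jj) {
        f <- em_haplotype_frequencies(dataset$geno[, idx[i]],
                                      dataset$geno[, jj])
        if (anyNA(f)) return(NA_real_)
        v <- r2_from_haplotypes(f)
        if (isTRUE(attr(v, "monomorphic"))) NA_real_ else as.numeric(v)
      }, numeric(1))
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, snp_a = map$snp_id[idx[i]], snp_b = map$snp_id[j],
        dist_bp = map$pos_bp[j] - pos[i], r2 = r2,
        stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(out)) do.call(rbind, out)
  else data.frame(chrom = character(), snp_a = character(),
                  snp_b = character(), dist_bp = numeric(), r2 = numeric())
  pairs <- pairs[!is.na(pairs$r2), , drop = FALSE]
  rownames(pairs) <- NULL

  bin <- cut(pairs$dist_bp / 1e6, dist_bins_mb, right = TRUE)
  stratum <- cut(pairs$r2, r2_breaks, include.lowest = TRUE)
  profile <- do.call(rbind, lapply(levels(bin), function(b) {
    sel <- which(!is.na(bin) & bin == b)
    if (!length(sel))
      return(data.frame(bin = b, stratum = levels(stratum), n = 0L,
                        proportion = NA_real_, mean_r2 = NA_real_))
    tb <- table(stratum[sel])
    data.frame(bin = b, stratum = names(tb), n = as.integer(tb),
               proportion = as.numeric(tb) / length(sel),
               mean_r2 = mean(pairs$r2[sel]))
  }))
  rownames(profile) <- NULL
  list(pairs = pairs, profile = profile)
}
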