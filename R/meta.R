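#' Weir-Cockerham F_ST for one biallelic locus, two populations
#'
#' The diploid theta estimator built from the moment components a
#' (among populations), b (among individuals within populations) and c
#' (within individuals). Negative finite-sample estimates are
#' preserved, not truncated.
#'
#' @param geno_line1,geno_line2 dosage vectors (0/1/2/NA), one per
#'   line; at least two non-missing individuals per line.
#' @return theta; `NA` when the locus is monomorphic across both lines
#'   (the estimator is undefined).
#' @export
weir_cockerham_fst <- function(geno_line1, geno_line2) {
  g1 <- geno_line1[!is.na(geno_line1)]
  g2 <- geno_line2[!is.na(geno_line2)]
  if (length(g1) < 2 || length(g2) < 2)
    stop("need >= 2 non-missing individuals per line")
  comp <- .wc_components(
    n = c(length(g1), length(g2)),
    p = c(mean(g1) / 2, mean(g2) / 2),
    h = c(mean(g1 == 1), mean(g2 == 1)))
  if (comp[["den"]] == 0) return(NA_real_)
  comp[["a"]] / comp[["den"]]
}

# WC84 variance components for r populations from per-pop sample size,
# allele frequency and observed heterozygosity
.wc_components <- function(n, p, h) {
  r <- length(n)
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  c(a = a, b = b, c = cc, den = a + b + cc)
}

# vectorised over the columns of a genotype matrix; NA where undefined
.wc_fst_matrix <- function(geno, line) {
  l1 <- line == unique(line)[1]
  g1 <- geno[l1, , drop = FALSE]; g2 <- geno[!l1, , drop = FALSE]
  n1 <- colSums(!is.na(g1)); n2 <- colSums(!is.na(g2))
  p1 <- colMeans(g1, na.rm = TRUE) / 2; p2 <- colMeans(g2, na.rm = TRUE) / 2
  h1 <- colMeans(g1 == 1, na.rm = TRUE); h2 <- colMeans(g2 == 1, na.rm = TRUE)
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 / 2 - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  den <- a + b + cc
  ifelse(den == 0, NA_real_, a / den)
}

#' Permutation p-values for line differentiation
#'
#' Per SNP, the observed Weir-Cockerham theta between the two founder
#' lines is compared with its distribution under random reassignment of
#' line labels: `p = (1 + #\{theta_perm >= theta_obs\}) / (n_perm + 1)`.
#' This is a documented stand-in for an external selection-signature
#' scan; real scan results can be supplied instead via
#' [read_selection_table()].
#'
#' @param founder_dataset a `peck_dataset` whose `ped$line` takes two
#'   values (HFP/LFP).
#' @param n_perm number of permutations (a warning is raised below
#'   100).
#' @param seed RNG seed for the permutations.
#' @return data.frame `snp_id`, `fst`, `p`; `p` is `NA` where theta is
#'   undefined (monomorphic across lines).
#' @export
selection_pvalues <- function(founder_dataset, n_perm = 10000L, seed = 1L) {
  line <- founder_dataset$ped$line
  if (length(unique(line)) != 2) stop("need exactly two founder lines")
  if (n_perm < 100) warning("fewer than 100 permutations")
  geno <- founder_dataset$geno
  obs <- .wc_fst_matrix(geno, line)
  set.seed(seed)
  exceed <- integer(ncol(geno))
  for (b in seq_len(n_perm)) {
    perm <- sample(line)
    thp <- .wc_fst_matrix(geno, perm)
    exceed <- exceed + (!is.na(thp) & !is.na(obs) & thp >= obs)
  }
  p <- (1 + exceed) / (n_perm + 1)
  p[is.na(obs)] <- NA_real_
  data.frame(snp_id = founder_dataset$map$snp_id, fst = obs, p = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fisher's combined probability test (k = 2)
#'
#' `chi2 = -2 (ln p1 + ln p2)` referred to a chi-square distribution
#' with `2k` degrees of freedom. Zero p-values are floored at 1e-300
#' before taking logs (permutation p-values have a positive floor
#' anyway).
#'
#' @param p_gwas,p_selection p-values in `[0, 1]` (vectorised).
#' @param k number of combined studies (default 2 -> 4 df).
#' @return list with `chi2_stat` and `p_meta`.
#' @export
fisher_combine <- function(p_gwas, p_selection, k = 2L) {
  if (any(c(p_gwas, p_selection) < 0 | c(p_gwas, p_selection) > 1,
          na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p1 <- pmax(p_gwas, 1e-300); p2 <- pmax(p_selection, 1e-300)
  stat <- -2 * (log(p1) + log(p2))
  list(chi2_stat = stat,
       p_meta = stats::pchisq(stat, df = 2 * k, lower.tail = FALSE))
}

#' Join association and selection-signature results and combine them
#'
#' Matches the two tables on SNP id, applies [fisher_combine()], and
#' re-derives genome-wide corrected p-values and Storey q-values on the
#' meta p-values with the same thresholds as the GWAS.
#'
#' @param gwas_results a `peck_assoc` data.frame.
#' @param selection_p_table data.frame `snp_id`, `fst`, `p`.
#' @param k number of combined studies.
#' @return data.frame: association columns plus `fst`, `p_selection`,
#'   `chi2_stat`, `p_meta`, `p_meta_genome_wide`, `q_meta`, `k`.
#'   Unmatched SNP ids are recorded in `attr(, "unmatched")`.
#' @export
run_meta <- function(gwas_results, selection_p_table, k = 2L) {
  sel <- selection_p_table
  i <- match(gwas_results$snp_id, sel$snp_id)
  if (all(is.na(i))) stop("no SNP ids shared between GWAS and selection table")
  out <- as.data.frame(gwas_results)
  out$fst <- sel$fst[i]
  out$p_selection <- sel$p[i]
  fc <- fisher_combine(out$p_nominal, out$p_selection, k = k)
  out$chi2_stat <- fc$chi2_stat
  out$p_meta <- fc$p_meta
  ok <- !is.na(out$p_meta)
  out$p_meta_genome_wide <- genome_wide_correct(out$p_meta, sum(ok))
  out$q_meta <- NA_real_
  if (any(ok)) out$q_meta[ok] <- storey_qvalues(out$p_meta[ok])
  out$k <- k
  attr(out, "unmatched") <-
    list(gwas_only = gwas_results$snp_id[is.na(i)],
         selection_only = setdiff(sel$snp_id, gwas_results$snp_id))
  out
}
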