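# Independent brute-force oracles used to cross-check the package's
# estimators. These deliberately take different computational routes
# than the implementations they verify.

# Poisson log-likelihood maximised numerically (BFGS), not by IRLS
oracle_poisson_loglik <- function(y, X, start = NULL) {
  nll <- function(beta) {
    eta <- drop(X %*% beta)
    -sum(stats::dpois(y, exp(eta), log = TRUE))
  }
  if (is.null(start)) start <- rep(0, ncol(X))
  opt <- stats::optim(start, nll, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  list(loglik = -opt$value, beta = opt$par)
}

# Weir-Cockerham theta via the three-level ANOVA sums of squares on the
# expanded allele table (pop / individual / allele), r = 2 populations
oracle_wc_anova <- function(g1, g2) {
  pops <- list(g1[!is.na(g1)], g2[!is.na(g2)])
  n <- lengths(pops)
  r <- 2
  alle <- lapply(pops, function(g) {
    a1 <- ifelse(g == 2, 1, ifelse(g == 1, 1, 0))
    a2 <- ifelse(g == 2, 1, 0)
    cbind(a1, a2)
  })
  ind_mean <- lapply(alle, rowMeans)
  pop_mean <- vapply(ind_mean, mean, numeric(1))
  grand <- sum(n * pop_mean) / sum(n)
  ssg <- sum(vapply(seq_len(r), function(i)
    sum((alle[[i]] - ind_mean[[i]])^2), numeric(1)))
  ssi <- 2 * sum(vapply(seq_len(r), function(i)
    sum((ind_mean[[i]] - pop_mean[i])^2), numeric(1)))
  ssp <- 2 * sum(n * (pop_mean - grand)^2)
  msg <- ssg / sum(n)
  msi <- ssi / sum(n - 1)
  msp <- ssp / (r - 1)
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  s2a <- (msp - msi) / (2 * nc)
  s2b <- (msi - msg) / 2
  s2c <- msg
  den <- s2a + s2b + s2c
  if (den == 0) return(NA_real_)
  s2a / den
}

# chi-square (df = 4) upper tail by numerical integration of the
# density x * exp(-x/2) / 4
oracle_chisq4_upper <- function(q) {
  if (q <= 0) return(1)
  stats::integrate(function(x) x * exp(-x / 2) / 4, q, Inf,
                   rel.tol = 1e-12)$value
}

# direct two-locus haplotype counting for data with no double
# heterozygotes (phase unambiguous)
oracle_direct_haplotypes <- function(a, b) {
  stopifnot(!any(a == 1 & b == 1))
  h <- c(p11 = 0, p10 = 0, p01 = 0, p00 = 0)
  for (i in seq_along(a)) {
    loc1 <- c(a[i] >= 1, a[i] == 2)   # two allele slots, TRUE = counted
    loc2 <- c(b[i] >= 1, b[i] == 2)
    # phase: at most one locus is het, pair the het allele arbitrarily
    for (k in 1:2) {
      key <- paste0("p", as.integer(loc1[k]), as.integer(loc2[k]))
      h[key] <- h[key] + 1
    }
  }
  h / sum(h)
}

withr_like_tempdir <- function(env = parent.frame()) {
  withr::local_tempdir(.local_envir = env)
}

# a small fully-specified F2-style dataset built in code
toy_dataset <- function(n = 24, n_snp = 6, seed = 99) {
  set.seed(seed)
  map <- data.frame(snp_id = sprintf("s%02d", seq_len(n_snp)),
                    chrom = "1", pos_bp = sort(sample.int(5e6, n_snp)))
  geno <- matrix(rbinom(n * n_snp, 2, 0.4), n, n_snp)
  ped <- data.frame(id = sprintf("h%02d", seq_len(n)),
                    sire = rep(c("s1", "s2"), each = n / 2),
                    dam = rep(sprintf("d%d", 1:4), each = n / 4),
                    hatch = rep(1:4, length.out = n), line = "F2",
                    stringsAsFactors = FALSE)
  ds <- new_peck_dataset(map, geno, ped)
  ds$pheno <- data.frame(id = ped$id, FPD = rpois(n, 5),
                         APD = rpois(n, 2), APR = rpois(n, 2),
                         observed_minutes = 420)
  ds
}
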