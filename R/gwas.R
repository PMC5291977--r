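#' Build the fixed-effects base design for the association model
#'
#' Intercept-free hatch indicators plus sire and dam factor levels with
#' first-level drop, as in the association model `eta = H_j + S_i + D_i
#' + b x`. Columns made redundant by nesting (each dam is mated to a
#' single sire, so dam indicators span the sire indicators) are dropped
#' by a pivoted QR so the returned matrix is full rank.
#'
#' @param dataset a `peck_dataset` with `hatch`, `sire`, `dam` in
#'   `$ped`.
#' @return numeric design matrix with `n_individuals` rows.
#' @export
build_design <- function(dataset) {
  ped <- dataset$ped
  stopifnot(!anyNA(ped$hatch))
  parts <- list(stats::model.matrix(~ 0 + factor(ped$hatch)))
  if (length(unique(ped$sire)) > 1)
    parts <- c(parts, list(stats::model.matrix(~ factor(ped$sire))[, -1,
                                                                   drop = FALSE]))
  if (length(unique(ped$dam)) > 1)
    parts <- c(parts, list(stats::model.matrix(~ factor(ped$dam))[, -1,
                                                                  drop = FALSE]))
  x <- do.call(cbind, parts)
  qx <- qr(x)
  x <- x[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
  colnames(x) <- make.names(colnames(x), unique = TRUE)
  x
}

#' Fit a Poisson log-link GLM
#'
#' Maximum-likelihood fit by iteratively reweighted least squares
#' (through `stats::glm.fit`), with an optional exposure offset
#' `log(exposure_minutes / 420)` that standardises counts to the
#' 420-minute observation window on the likelihood scale instead of
#' rescaling the counts themselves. Non-convergence and separation
#' (coefficients diverging towards +-infinity) are flagged rather than
#' raised.
#'
#' @param y non-negative integer counts.
#' @param design full-rank numeric model matrix.
#' @param exposure_minutes optional per-observation observed minutes.
#' @param tol IRLS deviance convergence tolerance.
#' @param max_iter IRLS iteration cap.
#' @param start optional starting coefficients (warm start).
#' @return object of class `peck_glm`: `coefficients`, `vcov`,
#'   `loglik`, `deviance`, `converged`, `flagged`, `n_used`.
#' @export
fit_poisson_glm <- function(y, design, exposure_minutes = NULL,
                            tol = 1e-8, max_iter = 100L, start = NULL) {
  design <- as.matrix(design)
  stopifnot(length(y) == nrow(design), all(y >= 0))
  offset <- NULL
  if (!is.null(exposure_minutes)) {
    stopifnot(length(exposure_minutes) == length(y), all(exposure_minutes > 0))
    offset <- log(exposure_minutes / 420)
  }
  fit <- suppressWarnings(stats::glm.fit(
    design, y, family = stats::poisson(), offset = offset, start = start,
    control = stats::glm.control(epsilon = tol, maxit = max_iter)))
  beta <- fit$coefficients
  sep <- anyNA(beta) || any(abs(beta) > 15) || !fit$converged
  vcov <- matrix(NA_real_, ncol(design), ncol(design))
  if (!anyNA(beta)) {
    w <- fit$weights
    xtwx <- crossprod(design * sqrt(w))
    ch <- tryCatch(chol(xtwx), error = function(e) NULL)
    if (!is.null(ch)) vcov <- chol2inv(ch) else sep <- TRUE
    # an effectively infinite standard error also signals separation
    if (!is.null(ch) && any(diag(vcov) > 1e4)) sep <- TRUE
  }
  dimnames(vcov) <- list(colnames(design), colnames(design))
  mu <- fit$fitted.values
  structure(list(coefficients = beta, vcov = vcov,
                 loglik = sum(stats::dpois(y, mu, log = TRUE)),
                 deviance = fit$deviance,
                 converged = fit$converged, flagged = sep,
                 n_used = length(y)),
            class = "peck_glm")
}

#' Wald test of the last coefficient of a fit
#' @param fit a `peck_glm`.
#' @param term coefficient name or index (default: last column).
#' @return list `b`, `se`, `z`, `p` (`p = NA` for flagged fits).
#' @export
wald_test <- function(fit, term = length(fit$coefficients)) {
  b <- fit$coefficients[[term]]
  se <- sqrt(fit$vcov[term, term])
  if (fit$flagged || !is.finite(b) || !is.finite(se) || se <= 0)
    return(list(b = b, se = se, z = NA_real_, p = NA_real_))
  z <- b / se
  list(b = b, se = se, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Single-marker Poisson association scan
#'
#' Per SNP, fits the count model with fixed hatch, sire and dam effects
#' plus the minor-allele dosage (additive model), or additionally a
#' heterozygosity indicator (dominance model), and reports the
#' two-sided Wald p-value for the SNP term (additive: `H0: b = 0`;
#' dominance: `H0: b_dom = 0`). Nominal p-values are then genome-wide
#' corrected with the Sidak-type formula over the number of tested SNPs
#' and FDR-adjusted with Storey q-values.
#'
#' @param dataset a QC'd `peck_dataset` with phenotypes attached.
#' @param trait one of the phenotype columns (e.g. `"FPD"`).
#' @param model `"additive"` or `"dominance"`.
#' @param use_exposure standardise to 420 observed minutes via a
#'   log-exposure offset (needs `observed_minutes`).
#' @param snps optional character vector restricting the scan.
#' @param n_correct number of tests used in the genome-wide correction;
#'   defaults to the number of SNPs actually tested.
#' @return data.frame of class `peck_assoc`: `snp_id`, `chrom`,
#'   `pos_bp`, `trait`, `model`, `maf`, `b_hat`, `se_b`, `p_nominal`,
#'   `p_genome_wide`, `q_value` (+ `dom_b_hat`, `dom_se`, `dom_p` for
#'   the dominance model). Skipped SNPs (monomorphic, flagged fits) are
#'   listed in `attr(, "skipped")`.
#' @export
snp_association <- function(dataset, trait, model = c("additive", "dominance"),
                            use_exposure = FALSE, snps = NULL,
                            n_correct = NULL) {
  model <- match.arg(model)
  stopifnot(!is.null(dataset$pheno), trait %in% names(dataset$pheno))
  y <- dataset$pheno[[trait]][match(dataset$ped$id, dataset$pheno$id)]
  stopifnot(!anyNA(y))
  expo <- NULL
  if (use_exposure) {
    stopifnot("observed_minutes" %in% names(dataset$pheno))
    expo <- dataset$pheno$observed_minutes[match(dataset$ped$id,
                                                 dataset$pheno$id)]
  }
  base <- build_design(dataset)
  snp_ids <- if (is.null(snps)) dataset$map$snp_id
  else intersect(dataset$map$snp_id, snps)
  cols <- match(snp_ids, dataset$map$snp_id)

  null_fit <- fit_poisson_glm(y, base, exposure_minutes = expo)
  nb <- length(null_fit$coefficients)
  maf_all <- maf_by_snp(dataset)

  nk <- length(cols)
  b_hat <- se_b <- p_nom <- rep(NA_real_, nk)
  dom_b <- dom_se <- dom_p <- add_p <- rep(NA_real_, nk)
  tested <- rep(FALSE, nk)
  skipped <- character(0); skip_reason <- character(0)
  for (k in seq_len(nk)) {
    j <- cols[k]
    x <- dataset$geno[, j]
    ok <- !is.na(x)
    xs <- x[ok]
    rng <- range(xs)
    if (rng[1] == rng[2]) {
      skipped <- c(skipped, snp_ids[k])
      skip_reason <- c(skip_reason, "monomorphic")
      next
    }
    if (model == "dominance") {
      z <- as.numeric(xs == 1)
      if (qr(cbind(1, xs, z))$rank < 3) {
        skipped <- c(skipped, snp_ids[k])
        skip_reason <- c(skip_reason, "dominance term aliased")
        next
      }
      X <- cbind(base[ok, , drop = FALSE], snp = xs, dom = z)
      st <- if (all(ok)) c(null_fit$coefficients, 0, 0) else NULL
    } else {
      X <- cbind(base[ok, , drop = FALSE], snp = xs)
      st <- if (all(ok)) c(null_fit$coefficients, 0) else NULL
    }
    fit <- fit_poisson_glm(y[ok], X, exposure_minutes = expo[ok], start = st)
    wt_add <- wald_test(fit, nb + 1L)
    tested[k] <- TRUE
    b_hat[k] <- wt_add$b; se_b[k] <- wt_add$se; p_nom[k] <- wt_add$p
    if (model == "dominance") {
      wt_dom <- wald_test(fit, nb + 2L)
      dom_b[k] <- wt_dom$b; dom_se[k] <- wt_dom$se; dom_p[k] <- wt_dom$p
      add_p[k] <- wt_add$p
      p_nom[k] <- wt_dom$p    # the dominance test is the reported one
    }
  }
  if (!any(tested)) stop("no testable SNPs")
  res <- data.frame(snp_id = snp_ids[tested],
                    chrom = dataset$map$chrom[cols[tested]],
                    pos_bp = dataset$map$pos_bp[cols[tested]],
                    trait = trait, model = model,
                    maf = maf_all[cols[tested]],
                    b_hat = b_hat[tested], se_b = se_b[tested],
                    p_nominal = p_nom[tested], stringsAsFactors = FALSE)
  if (model == "dominance") {
    res$dom_b_hat <- dom_b[tested]; res$dom_se <- dom_se[tested]
    res$dom_p <- dom_p[tested]; res$add_p <- add_p[tested]
  }
  m <- if (is.null(n_correct)) sum(!is.na(res$p_nominal)) else n_correct
  res$p_genome_wide <- genome_wide_correct(res$p_nominal, m)
  res$q_value <- NA_real_
  ok <- !is.na(res$p_nominal)
  if (any(ok)) res$q_value[ok] <- storey_qvalues(res$p_nominal[ok])
  rownames(res) <- NULL
  attr(res, "skipped") <- data.frame(snp_id = skipped, reason = skip_reason,
                                     stringsAsFactors = FALSE)
  attr(res, "n_correct") <- m
  class(res) <- c("peck_assoc", "data.frame")
  res
}

#' Sidak-type genome-wide correction
#'
#' `p_gw = 1 - (1 - p)^n_snps`, evaluated in log space
#' (`-expm1(n * log1p(-p))`) so that very small nominal p-values do not
#' underflow. Monotone increasing in both arguments.
#'
#' @param p_nominal nominal p-value(s) in `[0, 1]`.
#' @param n_snps number of tests (>= 1).
#' @return corrected p-value(s) in `[0, 1]`.
#' @export
genome_wide_correct <- function(p_nominal, n_snps) {
  stopifnot(n_snps >= 1)
  if (any(p_nominal < 0 | p_nominal > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  -expm1(n_snps * log1p(-p_nominal))
}

#' Storey FDR q-values
#'
#' Estimates the null proportion pi0 on the lambda grid 0.05..0.95
#' (step 0.05) with a cubic smoothing spline extrapolated to lambda = 1
#' (for fewer than 100 p-values, the single-point estimate at
#' lambda = 0.5 is used), then computes
#' `q_(i) = min_(j >= i) pi0 * m * p_(j) / j` by a step-up pass,
#' clipped to `[0, 1]`. With `pi0 = 1` the result equals
#' Benjamini-Hochberg adjusted p-values. The largest q-value among the
#' declared significant SNPs estimates the proportion of false
#' positives among them.
#'
#' @param p_vector p-values in `[0, 1]`.
#' @param pi0 optional fixed null proportion (overrides estimation).
#' @param lambda grid for pi0 estimation.
#' @return q-values in input order; `attr(, "pi0")` holds the estimate.
#' @export
storey_qvalues <- function(p_vector, pi0 = NULL,
                           lambda = seq(0.05, 0.95, 0.05)) {
  m <- length(p_vector)
  if (m == 0) stop("empty p-value vector")
  if (any(p_vector < 0 | p_vector > 1)) stop("p-values must lie in [0, 1]")
  if (is.null(pi0)) {
    if (m < 100) {
      pi0 <- mean(p_vector > 0.5) / 0.5
    } else {
      pi0_l <- vapply(lambda, function(l) mean(p_vector > l) / (1 - l),
                      numeric(1))
      sp <- stats::smooth.spline(lambda, pi0_l, df = 3)
      pi0 <- stats::predict(sp, x = 1)$y
    }
    pi0 <- min(max(pi0, 1 / m), 1)
  }
  o <- order(p_vector)
  q <- pi0 * m * p_vector[o] / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  attr(out, "pi0") <- pi0
  out
}
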