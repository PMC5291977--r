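#' Simulation configuration for the divergent-line F2 design
#'
#' Bundles every parameter of the synthetic-data generator: the SNP map,
#' the founder-line divergence, the QTL truth, the fixed-effect structure
#' of the count phenotypes, the mating design and the expression-array
#' layout. Defaults reproduce the study design the package emulates:
#' two White-Leghorn lines divergently selected for feather pecking,
#' 5 sires x 10 dams per line founding 10 F1 families, 10 F1 sires each
#' mated to 8 F1 hens, 960 F2 offspring in 4 hatches, and a 9-vs-9
#' brain expression comparison between the founder lines.
#'
#' @param n_snps total number of SNPs on the map.
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#'   Defaults to approximate sizes of chicken chromosomes GGA1-GGA9.
#' @param founder_divergence target mean Weir-Cockerham F_ST between the
#'   two founder lines, in `[0, 1)`.
#' @param n_qtl number of causal SNPs for the FPD-like trait.
#' @param qtl_add,qtl_dom additive effect b (log-rate per minor-allele
#'   copy) and dominance effect (log-rate bump for heterozygotes) given
#'   to each QTL; recycled to `n_qtl`.
#' @param qtl_freq_shift extra between-line allele-frequency separation
#'   applied at QTL SNPs, in `[0, 1]`; 1 fixes alternate alleles in the
#'   two lines. The shift decays into the flanks with scale
#'   `qtl_sweep_scale_bp`, emulating hitchhiking around a selected
#'   locus.
#' @param qtl_sweep_scale_bp exponential decay length (bp) of the QTL
#'   frequency shift into flanking SNPs; 0 confines the shift to the
#'   QTL SNP itself.
#' @param founder_ld_scale_bp correlation length (bp) of within-line
#'   haplotype LD: founder haplotypes are drawn by a first-order Markov
#'   process whose adjacent-SNP allele correlation is
#'   `exp(-distance / founder_ld_scale_bp)`; 0 gives within-line
#'   linkage equilibrium.
#' @param baseline_log_rate intercept of the linear predictor (log counts
#'   per 420 observed minutes).
#' @param hatch_effects numeric vector of fixed hatch effects, one per
#'   hatch (log scale).
#' @param sire_dam_effect_sd SD of the i.i.d. Gaussian sire and dam
#'   effects on the log scale; must be >= 0.
#' @param cm_per_mb genetic map density used for gamete formation
#'   (Haldane model, no interference).
#' @param design list with the mating design counts; see Details.
#' @param expression list with `n_probes`, `n_samples_per_line`,
#'   `cis_fraction` (fraction of in-cluster probes receiving a line
#'   shift), `cis_effect_sd` (SD of that shift, log2 scale) and
#'   `noise_sd` (residual SD, log2 scale).
#' @param seed integer seed; the same configuration always yields
#'   bit-identical data.
#'
#' @details The design list has elements `n_founder_sires_per_line` (5),
#' `n_founder_dams_per_line` (10), `n_f1_sires` (10),
#' `n_f1_dams_per_sire` (8), `n_hatches` (4) and `n_f2` (960); `n_f2`
#' must be divisible by `n_f1_sires * n_f1_dams_per_sire * n_hatches`.
#'
#' @return An object of class `peck_sim_config`.
#' @export
sim_config <- function(n_snps = 29376,
                       chrom_lengths = c(`1` = 196e6, `2` = 149e6, `3` = 111e6,
                                         `4` = 91e6, `5` = 60e6, `6` = 36e6,
                                         `7` = 38e6, `8` = 30e6, `9` = 24e6),
                       founder_divergence = 0.3,
                       n_qtl = 0,
                       qtl_add = 0.3,
                       qtl_dom = 0,
                       qtl_freq_shift = 0.6,
                       qtl_sweep_scale_bp = 1e6,
                       founder_ld_scale_bp = 1e6,
                       baseline_log_rate = log(5),
                       hatch_effects = c(0, 0.15, -0.1, 0.05),
                       sire_dam_effect_sd = 0.1,
                       cm_per_mb = 1,
                       design = list(),
                       expression = list(),
                       seed = 1L) {
  stopifnot(n_snps >= 1, length(chrom_lengths) >= 1, !is.null(names(chrom_lengths)))
  if (founder_divergence < 0 || founder_divergence >= 1)
    stop("founder_divergence must lie in [0, 1)")
  if (sire_dam_effect_sd < 0) stop("sire_dam_effect_sd must be >= 0")
  if (qtl_freq_shift < 0 || qtl_freq_shift > 1)
    stop("qtl_freq_shift must lie in [0, 1]")
  des <- utils::modifyList(list(n_founder_sires_per_line = 5L,
                                n_founder_dams_per_line = 10L,
                                n_f1_sires = 10L,
                                n_f1_dams_per_sire = 8L,
                                n_hatches = 4L,
                                n_f2 = 960L), design)
  if (length(hatch_effects) != des$n_hatches)
    stop("hatch_effects must have one entry per hatch")
  per_mating <- des$n_f2 / (des$n_f1_sires * des$n_f1_dams_per_sire)
  if (per_mating != round(per_mating) || (per_mating %% des$n_hatches) != 0)
    stop("n_f2 must divide evenly over matings and hatches")
  expr <- utils::modifyList(list(n_probes = 1200L, n_samples_per_line = 9L,
                                 cis_fraction = 0.1, cis_effect_sd = 0.75,
                                 noise_sd = 0.25), expression)
  if (expr$n_samples_per_line < 2)
    stop("n_samples_per_line must be >= 2 (Welch test undefined otherwise)")
  cfg <- list(n_snps = as.integer(n_snps), chrom_lengths = chrom_lengths,
              founder_divergence = founder_divergence, n_qtl = as.integer(n_qtl),
              qtl_add = rep_len(qtl_add, n_qtl), qtl_dom = rep_len(qtl_dom, n_qtl),
              qtl_freq_shift = qtl_freq_shift,
              qtl_sweep_scale_bp = qtl_sweep_scale_bp,
              founder_ld_scale_bp = founder_ld_scale_bp,
              baseline_log_rate = baseline_log_rate,
              hatch_effects = hatch_effects,
              sire_dam_effect_sd = sire_dam_effect_sd,
              cm_per_mb = cm_per_mb, design = des, expression = expr,
              seed = as.integer(seed))
  class(cfg) <- "peck_sim_config"
  cfg
}

#' Draw the SNP map implied by a configuration
#'
#' SNPs are spread over chromosomes proportionally to physical length,
#' with sorted uniform positions (1-based bp).
#'
#' @param cfg a [sim_config()] object.
#' @return data.frame with `snp_id`, `chrom`, `pos_bp`, sorted by
#'   (chrom, pos_bp) in the order of `cfg$chrom_lengths`.
#' @export
sim_snp_map <- function(cfg) {
  set.seed(cfg$seed)
  len <- cfg$chrom_lengths
  n_per <- pmax(1L, round(cfg$n_snps * len / sum(len)))
  # adjust rounding drift on the largest chromosome
  n_per[which.max(len)] <- n_per[which.max(len)] + cfg$n_snps - sum(n_per)
  map <- do.call(rbind, lapply(seq_along(len), function(i) {
    pos <- sort(sample.int(len[i], n_per[i]))
    data.frame(chrom = names(len)[i], pos_bp = pos)
  }))
  map$snp_id <- sprintf("snp_%s_%d", map$chrom, map$pos_bp)
  rownames(map) <- NULL
  map[, c("snp_id", "chrom", "pos_bp")]
}

#' Simulate founder-line allele frequencies
#'
#' Each SNP receives an ancestral frequency from Uniform(0.1, 0.9) and
#' line-specific frequencies from a Balding-Nichols (beta) divergence
#' model. The beta parameter is calibrated so that the expected
#' Weir-Cockerham F_ST between the two lines across SNPs approximates
#' `cfg$founder_divergence`. QTL SNPs additionally have their line
#' frequencies pushed apart by `cfg$qtl_freq_shift` (1 = fixed
#' difference), mimicking loci dragged by 11 generations of divergent
#' selection.
#'
#' @param cfg a [sim_config()] object.
#' @return data.frame with `snp_id`, `chrom`, `pos_bp`, `p_anc`,
#'   `p_hfp`, `p_lfp`, `is_qtl`, `qtl_add`, `qtl_dom`.
#' @export
simulate_founder_lines <- function(cfg) {
  map <- sim_snp_map(cfg)
  set.seed(cfg$seed + 1L)
  m <- nrow(map)
  p_anc <- stats::runif(m, 0.1, 0.9)
  t <- cfg$founder_divergence
  if (t == 0) {
    p_h <- p_l <- p_anc
  } else {
    f_bn <- .calibrate_bn(t)
    shp <- (1 - f_bn) / f_bn
    p_h <- stats::rbeta(m, p_anc * shp, (1 - p_anc) * shp)
    p_l <- stats::rbeta(m, p_anc * shp, (1 - p_anc) * shp)
  }
  is_qtl <- rep(FALSE, m)
  add <- dom <- rep(0, m)
  if (cfg$n_qtl > 0) {
    if (cfg$n_qtl > m) stop("more QTL than SNPs")
    qtl_idx <- sort(sample.int(m, cfg$n_qtl))
    is_qtl[qtl_idx] <- TRUE
    add[qtl_idx] <- cfg$qtl_add
    dom[qtl_idx] <- cfg$qtl_dom
    # hitchhiking: the selected shift decays into the flanks, leaving a
    # local divergence halo around each QTL (max over nearby sweeps)
    sweep <- rep(0, m)
    for (q in qtl_idx) {
      same <- map$chrom == map$chrom[q]
      d <- abs(map$pos_bp - map$pos_bp[q])
      dec <- ifelse(same,
                    if (cfg$qtl_sweep_scale_bp > 0)
                      exp(-d / cfg$qtl_sweep_scale_bp)
                    else as.numeric(d == 0), 0)
      sweep <- pmax(sweep, cfg$qtl_freq_shift * dec)
    }
    sweep[qtl_idx] <- cfg$qtl_freq_shift
    p_h <- p_anc + sweep * (1 - p_anc) + (1 - sweep) * (p_h - p_anc)
    p_l <- p_anc * (1 - sweep) + (1 - sweep) * (p_l - p_anc)
  }
  cbind(map, data.frame(p_anc = p_anc, p_hfp = p_h, p_lfp = p_l,
                        is_qtl = is_qtl, qtl_add = add, qtl_dom = dom))
}

# Draw n_hap founder haplotypes with within-line LD: a first-order
# Markov process over SNPs whose adjacent-allele correlation is
# exp(-d / scale) while keeping the marginal frequency of SNP j at
# p[j]. Conditional probabilities outside [0,1] are clamped (slight
# marginal distortion only near fixation). Returns n_hap x m 0/1.
.draw_haplotypes <- function(p, chrom, pos, n_hap, scale) {
  m <- length(p)
  H <- matrix(0L, n_hap, m)
  prev <- 0L
  for (j in seq_len(m)) {
    new_chrom <- j == 1 || chrom[j] != chrom[j - 1]
    if (scale <= 0 || new_chrom) {
      H[, j] <- stats::rbinom(n_hap, 1, p[j])
    } else {
      rho <- exp(-(pos[j] - pos[j - 1]) / scale)
      v_prev <- p[j - 1] * (1 - p[j - 1])
      v_cur <- p[j] * (1 - p[j])
      if (v_prev <= 0 || v_cur <= 0) {
        H[, j] <- stats::rbinom(n_hap, 1, p[j])
      } else {
        cond <- p[j] + rho * sqrt(v_cur / v_prev) * (H[, j - 1] - p[j - 1])
        H[, j] <- stats::rbinom(n_hap, 1, pmin(1, pmax(0, cond)))
      }
    }
  }
  H
}

# Mean per-SNP WC F_ST (large-sample limit theta = s2/(pq_bar + s2/2))
# between two Balding-Nichols populations at beta parameter f, averaged
# over ancestral frequencies ~ U(0.1, 0.9). Fixed-seed Monte Carlo on an
# isolated RNG stream so the enclosing simulation is unaffected.
.mean_fst_bn <- function(f, n_mc = 40000L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(20170203L)
  p <- stats::runif(n_mc, 0.1, 0.9)
  shp <- (1 - f) / f
  p1 <- stats::rbeta(n_mc, p * shp, (1 - p) * shp)
  p2 <- stats::rbeta(n_mc, p * shp, (1 - p) * shp)
  s2 <- (p1 - p2)^2 / 2
  pb <- (p1 + p2) / 2
  th <- s2 / (pb * (1 - pb) + s2 / 2)
  mean(th[is.finite(th)])
}

.bn_cache <- new.env(parent = emptyenv())

# invert .mean_fst_bn numerically; memoised per target. The mean
# per-SNP estimate saturates well below 1 under U(0.1, 0.9) ancestral
# frequencies (fixed loci have an undefined theta and drop out), so
# unreachable targets fall back to maximal divergence.
.calibrate_bn <- function(target) {
  key <- format(target, digits = 12)
  if (!is.null(.bn_cache[[key]])) return(.bn_cache[[key]])
  f_hi <- 0.999
  f <- if (.mean_fst_bn(f_hi) <= target) f_hi
  else stats::uniroot(function(f) .mean_fst_bn(f) - target,
                      c(1e-6, f_hi), tol = 1e-5)$root
  .bn_cache[[key]] <- f
  f
}

# gamete from a parent's two haplotypes (rows over SNPs, split by chrom)
# chrom_idx: list of SNP index vectors per chromosome (map order)
# morgans:   per-chromosome genetic lengths
.gamete <- function(h1, h2, chrom_idx, pos_list, morgans) {
  g <- integer(length(h1))
  for (k in seq_along(chrom_idx)) {
    idx <- chrom_idx[[k]]
    n_xo <- stats::rpois(1, morgans[k])
    phase <- stats::rbinom(1, 1, 0.5)
    if (n_xo > 0 && length(idx) > 1) {
      pos <- pos_list[[k]]
      xo <- sort(stats::runif(n_xo, 0, max(pos)))
      seg <- findInterval(pos, xo)        # crossovers flip the phase
      take1 <- (seg + phase) %% 2 == 0
    } else {
      take1 <- rep(phase == 0, length(idx))
    }
    g[idx] <- ifelse(take1, h1[idx], h2[idx])
  }
  g
}

#' Simulate the reciprocal F2 cross
#'
#' Founder genotypes are drawn from the line frequencies, F1 families are
#' formed by reciprocal line crossing (HFP sire x LFP dams and vice
#' versa), and F2 offspring by gamete formation with Haldane
#' recombination at `cfg$cm_per_mb`. Every F2 hen records its F1 sire,
#' F1 dam and hatch (assigned in equal groups per mating).
#'
#' @param cfg a [sim_config()] object.
#' @param line_freqs output of [simulate_founder_lines()].
#' @return list of class `peck_cross` with elements
#'   `dataset` (a `peck_dataset`, see [new_peck_dataset()]: the F2),
#'   `founders` (genotype matrix + line labels), `f1` (genotype matrices
#'   of F1 sires and dams), `parents` (haplotype bookkeeping used for
#'   Mendelian checks) and `truth` (QTL positions and effects).
#' @export
simulate_f2_cross <- function(cfg, line_freqs) {
  if (anyNA(line_freqs$p_hfp) || anyNA(line_freqs$p_lfp))
    stop("missing founder frequency")
  set.seed(cfg$seed + 2L)
  des <- cfg$design
  m <- nrow(line_freqs)
  chroms <- unique(line_freqs$chrom)
  chrom_idx <- lapply(chroms, function(ch) which(line_freqs$chrom == ch))
  pos_list <- lapply(chrom_idx, function(ix) line_freqs$pos_bp[ix])
  morgans <- vapply(seq_along(chroms), function(k)
    cfg$chrom_lengths[[chroms[k]]] * cfg$cm_per_mb / 1e8, numeric(1))

  n_fs <- des$n_founder_sires_per_line; n_fd <- des$n_founder_dams_per_line
  founder <- function(line, n) {
    p <- if (line == "HFP") line_freqs$p_hfp else line_freqs$p_lfp
    H <- .draw_haplotypes(p, line_freqs$chrom, line_freqs$pos_bp, 2L * n,
                          cfg$founder_ld_scale_bp)
    lapply(seq_len(n), function(i)
      list(h1 = H[2L * i - 1L, ], h2 = H[2L * i, ]))
  }
  fs_h <- founder("HFP", n_fs); fd_h <- founder("HFP", n_fd)
  fs_l <- founder("LFP", n_fs); fd_l <- founder("LFP", n_fd)

  # 10 F1 families: HFP sire i x two LFP dams, and reciprocally
  fam_sire <- c(fs_h, fs_l)
  fam_dams <- c(lapply(seq_len(n_fs), function(i) fd_l[c(2 * i - 1, 2 * i)]),
                lapply(seq_len(n_fs), function(i) fd_h[c(2 * i - 1, 2 * i)]))
  n_fam <- length(fam_sire)

  cross_ind <- function(sire, dam)
    list(h1 = .gamete(sire$h1, sire$h2, chrom_idx, pos_list, morgans),
         h2 = .gamete(dam$h1, dam$h2, chrom_idx, pos_list, morgans))

  # one F1 sire per family; F1 hens spread over families
  f1_sires <- lapply(seq_len(n_fam), function(f)
    cross_ind(fam_sire[[f]], fam_dams[[f]][[1 + (f %% 2)]]))
  n_f1_dams <- des$n_f1_sires * des$n_f1_dams_per_sire
  f1_dam_fam <- rep_len(seq_len(n_fam), n_f1_dams)
  f1_dams <- lapply(seq_len(n_f1_dams), function(i) {
    f <- f1_dam_fam[i]
    cross_ind(fam_sire[[f]], fam_dams[[f]][[1 + (i %% 2)]])
  })

  # mate F1 sire s with F1 hens from other families: shift family by one
  mate_of <- matrix(0L, des$n_f1_sires, des$n_f1_dams_per_sire)
  for (s in seq_len(des$n_f1_sires)) {
    fam <- (s %% n_fam) + 1L                # never the sire's own family
    pick <- which(f1_dam_fam == fam)
    mate_of[s, ] <- rep_len(pick, des$n_f1_dams_per_sire)
  }

  per_mating <- des$n_f2 %/% (des$n_f1_sires * des$n_f1_dams_per_sire)
  n_f2 <- des$n_f2
  geno <- matrix(0L, n_f2, m)
  h1m <- matrix(0L, n_f2, m); h2m <- matrix(0L, n_f2, m)
  sire_id <- character(n_f2); dam_id <- character(n_f2); hatch <- integer(n_f2)
  row <- 0L
  for (s in seq_len(des$n_f1_sires)) {
    for (d in seq_len(des$n_f1_dams_per_sire)) {
      dm <- mate_of[s, d]
      for (o in seq_len(per_mating)) {
        row <- row + 1L
        off <- cross_ind(f1_sires[[s]], f1_dams[[dm]])
        h1m[row, ] <- off$h1; h2m[row, ] <- off$h2
        geno[row, ] <- off$h1 + off$h2
        sire_id[row] <- sprintf("F1S%02d", s)
        dam_id[row] <- sprintf("F1D%02d", dm)
        hatch[row] <- 1L + (o - 1L) %% des$n_hatches
      }
    }
  }
  ids <- sprintf("F2_%04d", seq_len(n_f2))
  rownames(geno) <- ids
  colnames(geno) <- line_freqs$snp_id

  ped <- data.frame(id = ids, sire = sire_id, dam = dam_id,
                    hatch = hatch, line = "F2", stringsAsFactors = FALSE)
  dataset <- new_peck_dataset(line_freqs[, c("snp_id", "chrom", "pos_bp")],
                              geno, ped)

  hapmat <- function(lst) t(vapply(lst, function(x) x$h1 + x$h2, integer(m)))
  founders <- list(
    geno = rbind(hapmat(c(fs_h, fd_h)), hapmat(c(fs_l, fd_l))),
    line = rep(c("HFP", "LFP"), times = c(n_fs + n_fd, n_fs + n_fd)))
  colnames(founders$geno) <- line_freqs$snp_id
  f1 <- list(sires = hapmat(f1_sires), dams = hapmat(f1_dams),
             mate_of = mate_of)
  colnames(f1$sires) <- colnames(f1$dams) <- line_freqs$snp_id

  truth <- line_freqs[line_freqs$is_qtl,
                      c("snp_id", "chrom", "pos_bp", "qtl_add", "qtl_dom")]
  structure(list(dataset = dataset, founders = founders, f1 = f1,
                 haplos = list(h1 = h1m, h2 = h2m), truth = truth,
                 cfg = cfg),
            class = "peck_cross")
}

#' Simulate count phenotypes under the fixed-effects Poisson model
#'
#' The linear predictor of hen i is
#' `eta_i = baseline + H[hatch_i] + S[sire_i] + D[dam_i] +
#'  sum_q (b_q x_iq + bdom_q z_iq)` with `x` the QTL dosage and `z` the
#' heterozygosity indicator; counts are Poisson(exp(eta)) (or negative
#' binomial when `overdispersion` is finite). The FPD-like trait carries
#' the QTL effects; APD- and APR-like traits are generated from the same
#' fixed-effect structure without QTL.
#'
#' @param cfg a [sim_config()] object.
#' @param cross a `peck_cross` from [simulate_f2_cross()].
#' @param overdispersion negative-binomial size parameter; `Inf`
#'   (default) gives pure Poisson counts.
#' @return the `peck_cross` with `dataset$pheno` filled (columns
#'   `id`, `FPD`, `APD`, `APR`, `observed_minutes`) and a `truth_pheno`
#'   element holding per-hen `eta` and `expected = exp(eta)`.
#' @export
simulate_count_phenotypes <- function(cfg, cross, overdispersion = Inf) {
  set.seed(cfg$seed + 3L)
  ds <- cross$dataset
  ped <- ds$ped
  n <- nrow(ped)
  sires <- sort(unique(ped$sire)); dams <- sort(unique(ped$dam))
  s_eff <- stats::rnorm(length(sires), 0, cfg$sire_dam_effect_sd)
  d_eff <- stats::rnorm(length(dams), 0, cfg$sire_dam_effect_sd)
  base_eta <- cfg$baseline_log_rate +
    cfg$hatch_effects[ped$hatch] +
    s_eff[match(ped$sire, sires)] + d_eff[match(ped$dam, dams)]
  eta <- base_eta
  if (nrow(cross$truth) > 0) {
    x <- ds$geno[, cross$truth$snp_id, drop = FALSE]
    eta <- eta + drop(x %*% cross$truth$qtl_add) +
      drop((x == 1L) %*% cross$truth$qtl_dom)
  }
  if (any(eta > 700)) stop("exp(eta) overflow for hen(s): ",
                           paste(ped$id[eta > 700], collapse = ", "))
  draw <- function(mu) {
    if (is.finite(overdispersion))
      stats::rnbinom(n, size = overdispersion, mu = mu)
    else stats::rpois(n, mu)
  }
  fpd <- draw(exp(eta))
  apd <- draw(exp(base_eta - 0.7))   # aggressive pecks are rarer events
  apr <- draw(exp(base_eta - 0.7))
  ds$pheno <- data.frame(id = ped$id, FPD = fpd, APD = apd, APR = apr,
                         observed_minutes = 420, stringsAsFactors = FALSE)
  cross$dataset <- ds
  cross$truth_pheno <- data.frame(id = ped$id, eta = eta,
                                  expected = exp(eta))
  cross
}

#' Simulate a two-line brain expression experiment
#'
#' Draws probe positions over the configured chromosomes, gives every
#' probe a Gaussian log2 baseline, and adds a line mean-shift (a cis
#' effect) to a fraction of the probes falling inside designated "true"
#' intervals, so that cluster-restricted differential-expression
#' enrichment is recoverable downstream.
#'
#' @param cfg a [sim_config()] object; expression parameters come from
#'   `cfg$expression`.
#' @param clusters_truth data.frame with `chrom`, `start_bp`, `end_bp`
#'   intervals that should harbour the shifted probes (may be empty).
#' @return list with `probes` (probe map: `probe_id`, `chrom`, `start`,
#'   `end`, 0-based half-open, plus `pos_bp` midpoint and `shifted`),
#'   `line_h`, `line_l` (probe x sample log2 matrices).
#' @export
simulate_expression <- function(cfg, clusters_truth = NULL) {
  ex <- cfg$expression
  if (ex$n_samples_per_line < 2) stop("need >= 2 samples per line")
  set.seed(cfg$seed + 4L)
  len <- cfg$chrom_lengths
  np <- ex$n_probes
  chrom <- sample(names(len), np, replace = TRUE, prob = len / sum(len))
  start <- vapply(chrom, function(ch) sample.int(len[[ch]] - 60L, 1L), integer(1))
  probes <- data.frame(probe_id = sprintf("probe_%05d", seq_len(np)),
                       chrom = chrom, start = start, end = start + 60L,
                       stringsAsFactors = FALSE)
  probes <- probes[order(probes$chrom, probes$start), ]
  rownames(probes) <- NULL
  probes$pos_bp <- probes$start + (probes$end - probes$start) %/% 2 + 1L

  inside <- rep(FALSE, np)
  if (!is.null(clusters_truth) && nrow(clusters_truth) > 0)
    for (i in seq_len(nrow(clusters_truth)))
      inside <- inside | (probes$chrom == clusters_truth$chrom[i] &
                            probes$pos_bp >= clusters_truth$start_bp[i] &
                            probes$pos_bp <= clusters_truth$end_bp[i])
  shifted <- inside & stats::runif(np) < ex$cis_fraction
  delta <- ifelse(shifted,
                  sample(c(-1, 1), np, replace = TRUE) *
                    abs(stats::rnorm(np, 0, ex$cis_effect_sd)), 0)
  probes$shifted <- shifted

  mu <- stats::rnorm(np, 8, 1.5)
  ns <- ex$n_samples_per_line
  noise <- function() matrix(stats::rnorm(np * ns, 0, ex$noise_sd), np, ns)
  line_h <- mu + delta + noise()
  line_l <- mu + noise()
  dimnames(line_h) <- list(probes$probe_id, sprintf("HFP_%d", seq_len(ns)))
  dimnames(line_l) <- list(probes$probe_id, sprintf("LFP_%d", seq_len(ns)))
  list(probes = probes, line_h = line_h, line_l = line_l)
}

#' Simulate a genotype panel of founder-line individuals
#'
#' Draws unrelated individuals from each founder line's allele
#' frequencies (no pedigree structure), as a stand-in panel for the
#' selection-signature scan carried out in the founder lines.
#'
#' @param cfg a [sim_config()] object.
#' @param line_freqs output of [simulate_founder_lines()].
#' @param n_per_line individuals per line.
#' @return a `peck_dataset` whose `ped$line` is `HFP`/`LFP`.
#' @export
simulate_founder_panel <- function(cfg, line_freqs, n_per_line = 30L) {
  set.seed(cfg$seed + 5L)
  m <- nrow(line_freqs)
  draw <- function(p, n) {
    H <- .draw_haplotypes(p, line_freqs$chrom, line_freqs$pos_bp, 2L * n,
                          cfg$founder_ld_scale_bp)
    H[seq(1, 2 * n, 2), , drop = FALSE] + H[seq(2, 2 * n, 2), , drop = FALSE]
  }
  geno <- rbind(draw(line_freqs$p_hfp, n_per_line),
                draw(line_freqs$p_lfp, n_per_line))
  colnames(geno) <- line_freqs$snp_id
  ids <- sprintf("%s_%03d", rep(c("HFP", "LFP"), each = n_per_line),
                 seq_len(2 * n_per_line))
  rownames(geno) <- ids
  ped <- data.frame(id = ids, sire = "0", dam = "0", hatch = NA_integer_,
                    line = rep(c("HFP", "LFP"), each = n_per_line),
                    stringsAsFactors = FALSE)
  new_peck_dataset(line_freqs[, c("snp_id", "chrom", "pos_bp")], geno, ped)
}
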