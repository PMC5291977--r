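small_chroms <- c(`1` = 40e6, `2` = 30e6, `3` = 25e6)

test_that("config validation rejects impossible parameters", {
  expect_error(sim_config(founder_divergence = 1), "founder_divergence")
  expect_error(sim_config(sire_dam_effect_sd = -1), "sire_dam")
  expect_error(sim_config(hatch_effects = c(0, 1)), "hatch")
  expect_error(sim_config(design = list(n_f2 = 961)), "divide")
  expect_error(sim_config(expression = list(n_samples_per_line = 1)),
               "Welch")
})

test_that("zero founder divergence gives identical line frequencies", {
  cfg <- sim_config(n_snps = 200, chrom_lengths = small_chroms,
                    founder_divergence = 0, seed = 3)
  fr <- simulate_founder_lines(cfg)
  expect_identical(fr$p_hfp, fr$p_lfp)
  expect_identical(fr$p_hfp, fr$p_anc)
})

test_that("founder divergence calibrates mean Weir-Cockerham F_ST", {
  cfg <- sim_config(n_snps = 5000, chrom_lengths = small_chroms,
                    founder_divergence = 0.3, seed = 1)
  fr <- simulate_founder_lines(cfg)
  pan <- simulate_founder_panel(cfg, fr, n_per_line = 200)
  fst <- peckscan:::.wc_fst_matrix(pan$geno, pan$ped$line)
  expect_lt(abs(mean(fst, na.rm = TRUE) - 0.3), 0.05)
})

test_that("a full QTL frequency shift yields a fixed difference, F_ST = 1", {
  cfg <- sim_config(n_snps = 50, chrom_lengths = small_chroms,
                    founder_divergence = 0.2, n_qtl = 3,
                    qtl_freq_shift = 1, seed = 5)
  fr <- simulate_founder_lines(cfg)
  qtl <- which(fr$is_qtl)
  expect_true(all(fr$p_hfp[qtl] == 1 & fr$p_lfp[qtl] == 0))
  pan <- simulate_founder_panel(cfg, fr, n_per_line = 12)
  for (j in qtl)
    expect_equal(weir_cockerham_fst(pan$geno[pan$ped$line == "HFP", j],
                                    pan$geno[pan$ped$line == "LFP", j]), 1)
})

test_that("the F2 cross realises the mating design", {
  cfg <- sim_config(n_snps = 60, chrom_lengths = small_chroms, seed = 11)
  fr <- simulate_founder_lines(cfg)
  cross <- simulate_f2_cross(cfg, fr)
  ped <- cross$dataset$ped
  expect_equal(nrow(ped), 960)
  expect_equal(length(unique(ped$sire)), 10)
  mates <- tapply(ped$dam, ped$sire, function(d) length(unique(d)))
  expect_true(all(mates == 8))
  expect_equal(as.vector(table(ped$hatch)), rep(240, 4))
})

test_that("a SNP fixed for alternate alleles segregates 1:2:1 in the F2", {
  cfg <- sim_config(n_snps = 40, chrom_lengths = small_chroms,
                    founder_divergence = 0.2, n_qtl = 1,
                    qtl_freq_shift = 1, seed = 8)
  fr <- simulate_founder_lines(cfg)
  cross <- simulate_f2_cross(cfg, fr)
  j <- which(fr$is_qtl)
  # all F1 heterozygous
  expect_true(all(cross$f1$sires[, j] == 1))
  expect_true(all(cross$f1$dams[, j] == 1))
  counts <- table(factor(cross$dataset$geno[, j], 0:2))
  gof <- chisq.test(counts, p = c(0.25, 0.5, 0.25))
  expect_gt(gof$p.value, 0.001)
})

test_that("gamete formation without recombination copies a whole parental haplotype", {
  set.seed(21)
  m <- 30
  h1 <- rbinom(m, 1, 0.5); h2 <- rbinom(m, 1, 0.5)
  g <- peckscan:::.gamete(h1, h2, list(seq_len(m)),
                          list(sort(sample.int(1e6, m))), morgans = 0)
  expect_true(identical(g, h1) || identical(g, h2))
})

test_that("every F2 genotype is Mendelian-consistent with its parents", {
  cfg <- sim_config(n_snps = 80, chrom_lengths = small_chroms,
                    founder_divergence = 0.4, seed = 13)
  fr <- simulate_founder_lines(cfg)
  cross <- simulate_f2_cross(cfg, fr)
  ds <- cross$dataset
  sire_idx <- as.integer(sub("F1S", "", ds$ped$sire))
  dam_idx <- as.integer(sub("F1D", "", ds$ped$dam))
  gs <- cross$f1$sires[sire_idx, , drop = FALSE]
  gd <- cross$f1$dams[dam_idx, , drop = FALSE]
  lo <- (gs == 2) + (gd == 2)
  hi <- (gs >= 1) + (gd >= 1)
  expect_true(all(ds$geno >= lo & ds$geno <= hi))
})

test_that("identical configurations reproduce bit-identical data", {
  cfg <- sim_config(n_snps = 50, chrom_lengths = small_chroms,
                    founder_divergence = 0.3, n_qtl = 2, seed = 17)
  run <- function() {
    fr <- simulate_founder_lines(cfg)
    simulate_count_phenotypes(cfg, simulate_f2_cross(cfg, fr))
  }
  a <- run(); b <- run()
  expect_identical(a$dataset$geno, b$dataset$geno)
  expect_identical(a$dataset$pheno, b$dataset$pheno)
})

test_that("counts follow the configured Poisson mean structure", {
  cfg <- sim_config(n_snps = 30, chrom_lengths = small_chroms,
                    founder_divergence = 0, baseline_log_rate = log(5),
                    hatch_effects = rep(0, 4), sire_dam_effect_sd = 0,
                    seed = 19)
  fr <- simulate_founder_lines(cfg)
  cross <- simulate_count_phenotypes(cfg, simulate_f2_cross(cfg, fr))
  expect_equal(cross$truth_pheno$expected, rep(5, 960), tolerance = 1e-12)
  m <- mean(cross$dataset$pheno$FPD)
  expect_lt(abs(m - 5), 3 * sqrt(5 / 960))
})

test_that("a single additive QTL produces the expected rate ratio", {
  cfg <- sim_config(n_snps = 30, chrom_lengths = small_chroms,
                    founder_divergence = 0, n_qtl = 1, qtl_add = 0.4,
                    hatch_effects = rep(0, 4), sire_dam_effect_sd = 0,
                    seed = 23)
  fr <- simulate_founder_lines(cfg)
  fr$p_hfp[fr$is_qtl] <- fr$p_lfp[fr$is_qtl] <- 0.5
  cross <- simulate_count_phenotypes(cfg, simulate_f2_cross(cfg, fr))
  x <- cross$dataset$geno[, fr$snp_id[fr$is_qtl]]
  y <- cross$dataset$pheno$FPD
  s0 <- sum(y[x == 0]); s2 <- sum(y[x == 2])
  ratio <- (s2 / sum(x == 2)) / (s0 / sum(x == 0))
  se_log <- sqrt(1 / s0 + 1 / s2)
  expect_lt(abs(log(ratio) - 0.8), 3 * se_log)
})

test_that("a pure dominance QTL raises heterozygote expectations only", {
  cfg <- sim_config(n_snps = 30, chrom_lengths = small_chroms,
                    founder_divergence = 0, n_qtl = 1, qtl_add = 0,
                    qtl_dom = 0.5, hatch_effects = rep(0, 4),
                    sire_dam_effect_sd = 0, seed = 29)
  fr <- simulate_founder_lines(cfg)
  cross <- simulate_count_phenotypes(cfg, simulate_f2_cross(cfg, fr))
  x <- cross$dataset$geno[, fr$snp_id[fr$is_qtl]]
  ex <- cross$truth_pheno$expected
  expect_gt(min(ex[x == 1]), max(ex[x != 1]))
})

test_that("expression simulation shifts probes only inside true intervals", {
  cfg <- sim_config(n_snps = 30, chrom_lengths = small_chroms,
                    expression = list(n_probes = 400, cis_fraction = 0.5,
                                      cis_effect_sd = 1, noise_sd = 0.2),
                    seed = 31)
  iv <- data.frame(chrom = "1", start_bp = 5e6, end_bp = 15e6)
  ex <- simulate_expression(cfg, iv)
  expect_true(all(ex$probes$chrom[ex$probes$shifted] == "1"))
  expect_true(all(ex$probes$pos_bp[ex$probes$shifted] >= 5e6 &
                    ex$probes$pos_bp[ex$probes$shifted] <= 15e6))
  expect_equal(dim(ex$line_h), c(400, 9))
  # without cis effects no probe is shifted
  cfg0 <- sim_config(n_snps = 30, chrom_lengths = small_chroms,
                     expression = list(n_probes = 200, cis_fraction = 0),
                     seed = 31)
  ex0 <- simulate_expression(cfg0, iv)
  expect_false(any(ex0$probes$shifted))
})
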