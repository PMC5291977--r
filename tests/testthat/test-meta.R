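test_that("Weir-Cockerham theta hits the fixation and no-differentiation limits", {
  expect_equal(weir_cockerham_fst(rep(2L, 10), rep(0L, 12)), 1)
  set.seed(127)
  g <- rbinom(20, 2, 0.4)
  expect_lte(weir_cockerham_fst(g, g), 0)
  expect_true(is.na(weir_cockerham_fst(rep(0L, 5), rep(0L, 5))))
  expect_error(weir_cockerham_fst(c(1L), rep(1L, 5)), ">= 2")
})

test_that("theta matches the ANOVA sums-of-squares oracle to 1e-10", {
  g1 <- c(rep(0L, 4), rep(1L, 2))           # AA:4, Aa:2
  g2 <- c(rep(1L, 2), rep(2L, 4))           # Aa:2, aa:4
  expect_equal(weir_cockerham_fst(g1, g2), oracle_wc_anova(g1, g2),
               tolerance = 1e-10)
  set.seed(131)
  for (i in 1:50) {
    a <- rbinom(sample(5:40, 1), 2, runif(1, 0.05, 0.95))
    b <- rbinom(sample(5:40, 1), 2, runif(1, 0.05, 0.95))
    th <- weir_cockerham_fst(a, b)
    if (is.na(th)) next
    expect_equal(th, oracle_wc_anova(a, b), tolerance = 1e-10)
  }
})

test_that("the vectorised theta agrees with the per-locus estimator", {
  set.seed(137)
  geno <- matrix(rbinom(30 * 25, 2, 0.4), 30, 25)
  line <- rep(c("HFP", "LFP"), each = 15)
  vec <- peckscan:::.wc_fst_matrix(geno, line)
  for (j in 1:25) {
    ref <- suppressWarnings(weir_cockerham_fst(geno[line == "HFP", j],
                                               geno[line == "LFP", j]))
    expect_equal(vec[j], ref, tolerance = 1e-12)
  }
})

test_that("permutation p-values behave at the extremes and under relabeling", {
  map <- data.frame(snp_id = c("fix", "same"), chrom = "1",
                    pos_bp = c(100, 200))
  n <- 15
  geno <- cbind(c(rep(2L, n), rep(0L, n)), rep(c(0L, 1L, 2L), 10))
  ped <- data.frame(id = sprintf("i%02d", 1:(2 * n)), sire = "0",
                    dam = "0", hatch = NA_integer_,
                    line = rep(c("HFP", "LFP"), each = n))
  ds <- new_peck_dataset(map, geno, ped)
  sel <- selection_pvalues(ds, n_perm = 499, seed = 139)
  expect_equal(sel$fst[sel$snp_id == "fix"], 1)
  expect_equal(sel$p[sel$snp_id == "fix"], 1 / 500)
  # identical allele distribution across lines -> p near 1
  expect_gt(sel$p[sel$snp_id == "same"], 0.5)
  # allele relabeling leaves p untouched
  ds2 <- ds; ds2$geno <- 2L - ds2$geno
  sel2 <- selection_pvalues(ds2, n_perm = 499, seed = 139)
  expect_equal(sel2$p, sel$p)
  expect_warning(selection_pvalues(ds, n_perm = 50, seed = 1), "100")
})

test_that("null permutation p-values are valid (conservative at every level)", {
  # theta takes few distinct values on discrete genotype compositions,
  # so the '>= with +1' convention produces heavy ties: the p-values
  # are stochastically larger than uniform (never anti-conservative)
  set.seed(149)
  m <- 400; n <- 30
  geno <- matrix(rbinom(2 * n * m, 2, runif(m, 0.2, 0.8)[rep(1:m, each = 2 * n)]),
                 2 * n, m)
  ds <- new_peck_dataset(
    data.frame(snp_id = paste0("s", 1:m), chrom = "1", pos_bp = 1:m * 1000),
    geno,
    data.frame(id = sprintf("i%02d", 1:(2 * n)), sire = "0", dam = "0",
               hatch = NA_integer_, line = rep(c("HFP", "LFP"), each = n)))
  sel <- selection_pvalues(ds, n_perm = 300, seed = 151)
  for (alpha in c(0.01, 0.05, 0.1, 0.25, 0.5)) {
    se <- sqrt(alpha * (1 - alpha) / m)
    expect_lte(mean(sel$p <= alpha), alpha + 3 * se)
  }
})

test_that("Fisher's method matches its closed form and symmetry", {
  fc <- fisher_combine(1, 1)
  expect_equal(fc$chi2_stat, 0)
  expect_equal(fc$p_meta, 1)
  a <- fisher_combine(0.013, 0.21); b <- fisher_combine(0.21, 0.013)
  expect_equal(a$chi2_stat, b$chi2_stat)
  expect_equal(a$p_meta, b$p_meta)
  fc2 <- fisher_combine(0.05, 0.05)
  expect_equal(fc2$chi2_stat, -4 * log(0.05), tolerance = 1e-12)
  expect_equal(fc2$p_meta, oracle_chisq4_upper(fc2$chi2_stat),
               tolerance = 1e-10)
  expect_error(fisher_combine(-0.1, 0.5), "0, 1")
  # p = 0 is floored, not NaN
  expect_true(is.finite(fisher_combine(0, 0.5)$chi2_stat))
})

test_that("combining two equal p-values below ~0.28 sharpens the evidence", {
  # the sharpening region of Fisher's method on the diagonal: for
  # unequal pairs (e.g. 0.2 with 0.27) the combined p can exceed the
  # smaller input, so the property is asserted where it actually holds
  p <- c(1e-6, 1e-4, 0.001, 0.01, 0.05, 0.1, 0.2, 0.27)
  fc <- fisher_combine(p, p)
  expect_true(all(fc$p_meta < p))
  # and just above the region it reverses
  expect_gt(fisher_combine(0.3, 0.3)$p_meta, 0.3)
})

test_that("run_meta joins on SNP id and is a monotone transform at null selection p", {
  ds <- toy_dataset(n = 48, n_snp = 6, seed = 157)
  res <- snp_association(ds, "FPD")
  sel <- data.frame(snp_id = res$snp_id, fst = 0.1, p = 1)
  met <- run_meta(res, sel)
  expect_equal(order(met$p_meta), order(met$p_nominal))
  expect_equal(met$chi2_stat, -2 * log(met$p_nominal), tolerance = 1e-12)
  # unmatched ids are reported; empty intersection errors
  sel2 <- sel; sel2$snp_id[1] <- "nope"
  met2 <- run_meta(res, sel2)
  expect_equal(attr(met2, "unmatched")$gwas_only, res$snp_id[1])
  sel3 <- sel; sel3$snp_id <- paste0("x", sel3$snp_id)
  expect_error(run_meta(res, sel3), "shared")
})

test_that("null GWAS and selection p-values are uncorrelated", {
  cfg <- sim_config(n_snps = 600, chrom_lengths = setNames(rep(15e6, 6),
                                                           1:6),
                    founder_divergence = 0.3, seed = 163)
  fr <- simulate_founder_lines(cfg)
  cross <- simulate_count_phenotypes(cfg, simulate_f2_cross(cfg, fr))
  ds <- orient_minor(cross$dataset)
  res <- snp_association(ds, "FPD")
  pan <- simulate_founder_panel(cfg, fr, n_per_line = 30)
  sel <- selection_pvalues(pan, n_perm = 300, seed = 167)
  met <- run_meta(res, sel)
  ok <- !is.na(met$p_nominal) & !is.na(met$p_selection)
  r <- cor(met$p_nominal[ok], met$p_selection[ok])
  expect_lt(abs(r), 0.08)
})
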