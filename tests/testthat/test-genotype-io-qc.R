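test_that("a small PED/MAP fixture reads with minor-allele orientation", {
  dir <- withr_like_tempdir()
  writeLines(c("1 s1 0 100",
               "1 s2 0 200"), file.path(dir, "toy.map"))
  # SNP1 alleles: hen1 AA, hen2 AA, hen3 AT -> A is major (5), T minor (1)
  # SNP2: hen1 GC, hen2 CC, hen3 00 (missing)
  writeLines(c("F f1 0 0 0 -9 A A G C",
               "F f2 0 0 0 -9 A A C C",
               "F f3 0 0 0 -9 A T 0 0"), file.path(dir, "toy.ped"))
  ds <- read_genotypes(file.path(dir, "toy.ped"))
  expect_equal(n_snps(ds), 2)
  expect_equal(n_individuals(ds), 3)
  expect_equal(unname(ds$geno[, "s1"]), c(0L, 0L, 1L))   # counts T
  expect_equal(unname(ds$geno[, "s2"]), c(1L, 0L, NA))   # counts G (minor)
})

test_that("PED parsing errors are located and duplicate ids rejected", {
  dir <- withr_like_tempdir()
  writeLines(c("1 s1 0 100"), file.path(dir, "bad.map"))
  writeLines(c("F f1 0 0 0 -9 A A",
               "F f2 0 0 0 -9 A"), file.path(dir, "bad.ped"))
  expect_error(read_genotypes(file.path(dir, "bad.ped")), "line 2")
  writeLines(c("1 s1 0 100", "1 s1 0 200"),
             file.path(dir, "dup.map"))
  writeLines("F f1 0 0 0 -9 A A G G", file.path(dir, "dup.ped"))
  expect_error(read_genotypes(file.path(dir, "dup.ped")), "duplicate")
})

test_that("write -> read round-trips the dosage matrix exactly", {
  cfg <- sim_config(n_snps = 40, chrom_lengths = c(`1` = 30e6, `2` = 20e6),
                    founder_divergence = 0.3, seed = 41)
  fr <- simulate_founder_lines(cfg)
  ds <- orient_minor(simulate_f2_cross(cfg, fr)$dataset)
  ds$geno <- ds$geno[1:40, , drop = FALSE]
  ds$ped <- ds$ped[1:40, ]
  dir <- withr_like_tempdir()
  write_ped_map(ds, file.path(dir, "rt"))
  back <- read_genotypes(file.path(dir, "rt.ped"))
  # orientation is only defined up to a flip at MAF exactly 0.5:
  # every column must match exactly or as its mirror image
  same <- vapply(seq_len(ncol(back$geno)), function(j) {
    a <- unname(back$geno[, j]); b <- unname(ds$geno[, j])
    identical(a, b) || identical(a, 2L - b)
  }, logical(1))
  expect_true(all(same))
  # the reader's own orientation contract: counted-allele frequency
  # never exceeds 0.5 in the loaded sample
  expect_true(all(colMeans(back$geno, na.rm = TRUE) / 2 <= 0.5))
  expect_equal(back$map$pos_bp, ds$map$pos_bp)
})

test_that("matrix TSV input is accepted", {
  dir <- withr_like_tempdir()
  writeLines(c("snp_id\tchrom\tpos_bp\th1\th2\th3",
               "s1\t1\t100\t0\t1\t2",
               "s2\t1\t200\t1\tNA\t0"), file.path(dir, "m.tsv"))
  ds <- read_genotypes(file.path(dir, "m.tsv"), format = "matrix_tsv")
  expect_equal(dim(ds$geno), c(3L, 2L))
  expect_equal(unname(ds$geno["h2", ]), c(1L, NA))
})

test_that("compute_maf folds, skips missing, and flags all-missing", {
  expect_equal(compute_maf(c(1, 1, 1, 1)), 0.5)
  expect_equal(compute_maf(c(0, 0, 0)), 0)
  expect_equal(compute_maf(c(0, 1, 2, 2, NA)), 0.375)
  expect_true(is.na(compute_maf(c(NA, NA))))
})

test_that("filtering applies chromosome, call-rate and MAF rules in order", {
  n <- 100
  mk <- function(maf, callrate) {
    g <- rep(0L, n)
    g[seq_len(round(2 * maf * n / 2) * 1)] <- 1L
    g[sample.int(n, n - round(callrate * n))] <- NA_integer_
    g
  }
  set.seed(43)
  geno <- cbind(rbinom(n, 2, 0.5),            # chrom 1, clean
                rbinom(n, 2, 0.4),            # chrom Z -> removed (rule 1)
                mk(0.4, 0.90),                # low call rate (rule 2)
                rbinom(n, 2, 0.01),           # low MAF (rule 3)
                rbinom(n, 2, 0.3))            # unassigned -> removed (rule 1)
  # force the MAF column under 0.03
  geno[, 4] <- c(rep(1L, 2), rep(0L, n - 2))  # MAF = 0.01
  map <- data.frame(snp_id = paste0("v", 1:5),
                    chrom = c("1", "Z", "1", "1", "unassigned"),
                    pos_bp = c(100, 200, 300, 400, 500))
  ped <- data.frame(id = sprintf("h%03d", 1:n), sire = "0", dam = "0",
                    hatch = 1L, line = "F2")
  ds <- new_peck_dataset(map, geno, ped)
  out <- filter_variants(ds)
  expect_equal(out$report$n_retained, 1L)
  expect_equal(out$dataset$map$snp_id, "v1")
  expect_equal(unname(out$report$n_removed),
               c(2L, 1L, 1L))
  # attribution: the Z SNP is counted under the chromosome rule only
  expect_true("v2" %in% out$report$removed$chromosome)
  # reconciliation
  expect_equal(out$report$n_input,
               out$report$n_retained + sum(out$report$n_removed))
  expect_equal(sum(lengths(out$report$removed)),
               sum(out$report$n_removed))
})

test_that("call-rate and MAF boundaries are kept (strict 'lower than')", {
  n <- 100
  g_cr <- c(rep(NA_integer_, 5), rbinom(n - 5, 2, 0.5))       # exactly 0.95
  g_maf <- c(rep(1L, 6), rep(0L, n - 6))                      # exactly 0.03
  ds <- new_peck_dataset(
    data.frame(snp_id = c("a", "b"), chrom = "1", pos_bp = c(1, 2)),
    cbind(g_cr, g_maf),
    data.frame(id = sprintf("h%03d", 1:n), sire = "0", dam = "0",
               hatch = 1L, line = "F2"))
  out <- filter_variants(ds)
  expect_equal(out$report$n_retained, 2L)
})

test_that("filtering is idempotent", {
  cfg <- sim_config(n_snps = 120, chrom_lengths = c(`1` = 30e6, Z = 20e6),
                    founder_divergence = 0.5, seed = 47)
  fr <- simulate_founder_lines(cfg)
  ds <- simulate_f2_cross(cfg, fr)$dataset
  once <- filter_variants(ds)
  twice <- filter_variants(once$dataset)
  expect_equal(sum(twice$report$n_removed), 0L)
  expect_equal(twice$dataset$map, once$dataset$map)
})
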