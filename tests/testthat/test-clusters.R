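mk_results <- function(pos_mb, p, chrom = "1") {
  data.frame(snp_id = sprintf("s%03d", seq_along(pos_mb)),
             chrom = chrom, pos_bp = pos_mb * 1e6, p = p,
             stringsAsFactors = FALSE)
}

test_that("the worked chaining example places bounds at the weak SNPs", {
  res <- mk_results(c(9.6, 10.0, 11.0, 12.0, 12.4),
                    c(4e-4, 1e-5, 0.5, 1e-5, 4e-4))
  cl <- build_clusters(res, p_col = "p")
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$start_bp, 9.6e6)
  expect_equal(cl$end_bp, 12.4e6)
  expect_equal(cl$midpoint_bp, 11e6)
  expect_equal(cl$n_sig, 2L)
  expect_equal(cl$n_weak, 4L)
})

test_that("isolated or too-distant significant SNPs never form a cluster", {
  expect_equal(nrow(build_clusters(mk_results(10, 1e-6), p_col = "p")), 0L)
  res <- mk_results(c(10.0, 13.5), c(1e-5, 1e-5))
  expect_equal(nrow(build_clusters(res, p_col = "p")), 0L)
  # exactly 3 Mb apart still chains (rule is a maximum distance)
  res3 <- mk_results(c(10.0, 13.0), c(1e-5, 1e-5))
  expect_equal(nrow(build_clusters(res3, p_col = "p")), 1L)
})

test_that("unsorted input is rejected", {
  res <- mk_results(c(12, 10), c(1e-5, 1e-5))
  expect_error(build_clusters(res, p_col = "p"), "sorted")
})

test_that("a chain wider than the flank window is truncated with a warning", {
  res <- mk_results(c(0.5, 3.4, 6.3), c(1e-5, 1e-5, 1e-5))
  expect_warning(cl <- build_clusters(res, p_col = "p"), "truncated")
  expect_equal(cl$midpoint_bp, 3.4e6)
  expect_equal(cl$start_bp, 3.4e6)
  expect_equal(cl$end_bp, 3.4e6)
})

test_that("cluster construction ignores duplicated non-significant SNPs", {
  res <- mk_results(c(9.6, 10.0, 11.0, 12.0, 12.4),
                    c(4e-4, 1e-5, 0.5, 1e-5, 4e-4))
  pad <- mk_results(c(10.5, 10.5, 11.5), c(0.9, 0.9, 0.8))
  pad$snp_id <- paste0("dup", 1:3)
  res2 <- rbind(res, pad)
  res2 <- res2[order(res2$pos_bp), ]
  a <- build_clusters(res, p_col = "p")
  b <- build_clusters(res2, p_col = "p")
  expect_equal(b$start_bp, a$start_bp)
  expect_equal(b$end_bp, a$end_bp)
  expect_equal(b$n_sig, a$n_sig)
})

test_that("lengths round half-up to two decimals", {
  expect_equal(cluster_length_mb(58834628, 59725450), 0.89)
  expect_equal(cluster_length_mb(37372218, 39828657), 2.46)
  expect_equal(cluster_length_mb(5650341, 7645421), 2.00)
  expect_equal(cluster_length_mb(100, 100), 0)
  expect_equal(cluster_length_mb(0, 5000), 0.01)   # 0.005 rounds up
  expect_error(cluster_length_mb(10, 5), "end_bp")
})

test_that("interval membership is inclusive at both bounds", {
  cl <- data.frame(cluster = 1L, chrom = "1", start_bp = 100, end_bp = 200)
  pos <- data.frame(snp_id = c("l", "a", "b", "r"), chrom = "1",
                    pos_bp = c(99, 100, 200, 201))
  hits <- snps_in_clusters(pos, cl)
  expect_equal(sort(hits$assignments$snp_id), c("a", "b"))
  expect_equal(hits$n_inside, 2L)
  empty <- snps_in_clusters(pos, cl[0, ])
  expect_equal(empty$n_inside, 0L)
})

test_that("cluster overlap detection respects chromosomes", {
  rep_cl <- reported_clusters()
  fpd <- rep_cl[rep_cl$trait == "FPD", ]
  meta <- rep_cl[rep_cl$trait == "FPD_meta", ]
  ov <- overlap_clusters(fpd, meta)
  # the single shared region between the plain and meta scans sits on GGA8
  expect_equal(nrow(ov), 1L)
  expect_equal(ov$chrom, "8")
  expect_equal(ov$cluster_a, 4L)
  expect_equal(ov$cluster_b, 8L)
  self <- overlap_clusters(fpd, fpd)
  expect_gte(nrow(self), nrow(fpd))
  disj <- overlap_clusters(fpd[fpd$chrom == "3", ],
                           meta[meta$chrom == "9", ])
  expect_equal(nrow(disj), 0L)
})

test_that("built clusters localise planted QTL", {
  # selective-sweep halos around each QTL provide the chained
  # significant SNPs; within-family co-segregation also throws weaker
  # same-chromosome echoes, so localisation is asserted at the
  # chromosome level (exact) and at 3 Mb (the chaining scale)
  tot <- 0L; on_qtl_chrom <- 0L; near <- 0L; rec <- 0L; n_qtl <- 0L
  for (seed in c(173, 5, 42)) {
    cfg <- sim_config(n_snps = 600, chrom_lengths = setNames(rep(30e6, 6),
                                                             1:6),
                      founder_divergence = 0.05, n_qtl = 3, qtl_add = 0.12,
                      qtl_freq_shift = 1, seed = seed)
    fr <- simulate_founder_lines(cfg)
    cross <- simulate_count_phenotypes(cfg, simulate_f2_cross(cfg, fr))
    res <- snp_association(orient_minor(cross$dataset), "FPD")
    cl <- suppressWarnings(build_clusters(res, trait = "FPD"))
    qtl <- cross$truth
    gap <- function(i, k) max(0, cl$start_bp[i] - qtl$pos_bp[k],
                              qtl$pos_bp[k] - cl$end_bp[i])
    for (i in seq_len(nrow(cl))) {
      tot <- tot + 1L
      same <- which(qtl$chrom == cl$chrom[i])
      if (length(same)) {
        on_qtl_chrom <- on_qtl_chrom + 1L
        if (min(vapply(same, gap, numeric(1), i = i)) <= 3e6)
          near <- near + 1L
      }
    }
    for (k in seq_len(nrow(qtl))) {
      n_qtl <- n_qtl + 1L
      same <- which(cl$chrom == qtl$chrom[k])
      if (length(same) &&
          min(vapply(same, gap, numeric(1), k = k)) <= 3e6)
        rec <- rec + 1L
    }
  }
  expect_gt(tot, 0)
  expect_equal(on_qtl_chrom, tot)     # no clusters on QTL-free chromosomes
  expect_gte(near / tot, 0.8)         # clusters sit at their QTL
  expect_gte(rec / n_qtl, 0.8)        # QTL are recovered by clusters
})
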