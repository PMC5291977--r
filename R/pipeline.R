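#' Run the full analysis chain on simulated or loaded data
#'
#' Sequences the stages: simulate (or load) genotypes and phenotypes,
#' SNP QC, per-trait Poisson GWAS, founder-line selection-signature
#' p-values, Fisher meta-analysis for FPD, cluster construction per
#' trait (including the meta trait), expression simulation restricted
#' to the FPD_meta clusters, differential expression and enrichment.
#' Optionally also the LD-decay profile. Every stage writes a TSV under
#' `out_dir` (when given) plus per-trait Manhattan data
#' (chrom, pos_bp, neg_log10_p) and a JSON run manifest with the
#' configuration, seed and row counts, sufficient to re-run
#' bit-identically.
#'
#' @param cfg a [sim_config()] (simulate block), or a list with
#'   elements `ped`, `map`, `pheno` naming input files to load.
#' @param out_dir output directory (created); `NULL` = no files.
#' @param traits traits to scan.
#' @param meta_trait trait receiving the Fisher meta-analysis
#'   (default `"FPD"`).
#' @param thresholds list: `sig` (5e-5), `weak` (5e-4), `gw` (0.05).
#' @param cluster_params list: `link_mb` (3), `flank_mb` (1.5).
#' @param selection list: `n_per_line` founder panel size, `n_perm`
#'   permutations; or a data.frame of externally supplied selection
#'   p-values (`snp_id`, `fst`, `p`).
#' @param run_ld compute the LD-decay profile (slowest stage; off by
#'   default).
#' @param run_expression simulate and analyse the expression stage.
#' @param quiet suppress per-stage log lines.
#' @return list with `dataset`, `qc`, `assoc` (per trait), `selection`,
#'   `meta`, `clusters` (per trait + meta), `expression`, `ld`,
#'   `manifest`.
#' @export
run_pipeline <- function(cfg, out_dir = NULL,
                         traits = c("FPD", "APD", "APR"),
                         meta_trait = "FPD",
                         thresholds = list(sig = 5e-5, weak = 5e-4, gw = 0.05),
                         cluster_params = list(link_mb = 3, flank_mb = 1.5),
                         selection = list(n_per_line = 30L, n_perm = 2000L),
                         run_ld = FALSE, run_expression = TRUE,
                         quiet = FALSE) {
  stopifnot(thresholds$sig <= thresholds$weak,
            thresholds$gw > 0, thresholds$gw < 1)
  say <- function(stage, ...) if (!quiet)
    message(sprintf("[%s] %s", stage, sprintf(...)))
  t_all <- list()

  if (inherits(cfg, "peck_sim_config")) {
    freqs <- simulate_founder_lines(cfg)
    cross <- simulate_f2_cross(cfg, freqs)
    cross <- simulate_count_phenotypes(cfg, cross)
    dataset <- orient_minor(cross$dataset)
    founder_panel <- if (is.data.frame(selection)) NULL
    else simulate_founder_panel(cfg, freqs,
                                n_per_line = selection$n_per_line)
    truth <- cross$truth
    say("simulate", "%d F2 x %d SNPs, %d QTL", n_individuals(dataset),
        n_snps(dataset), nrow(truth))
  } else {
    dataset <- read_genotypes(cfg$ped)
    dataset <- attach_phenotypes(dataset, read_phenotypes(cfg$pheno))
    dataset <- orient_minor(dataset)
    founder_panel <- NULL
    truth <- NULL
    say("load", "%d individuals x %d SNPs", n_individuals(dataset),
        n_snps(dataset))
  }

  qc <- filter_variants(dataset)
  dataset <- qc$dataset
  say("qc", "%d of %d SNPs retained", qc$report$n_retained,
      qc$report$n_input)

  ld <- NULL
  if (run_ld) {
    ld <- ld_decay_profile(dataset)
    say("ld", "%d pairs profiled", nrow(ld$pairs))
  }

  assoc <- list()
  for (tr in traits) {
    assoc[[tr]] <- snp_association(dataset, tr)
    say("gwas", "%s: %d SNPs tested, %d significant at %g", tr,
        sum(!is.na(assoc[[tr]]$p_nominal)),
        sum(assoc[[tr]]$p_nominal <= thresholds$sig, na.rm = TRUE),
        thresholds$sig)
  }

  sel_tab <- if (is.data.frame(selection)) selection
  else if (!is.null(founder_panel))
    selection_pvalues(founder_panel, n_perm = selection$n_perm,
                      seed = cfg$seed + 6L)
  meta <- NULL
  if (!is.null(sel_tab) && meta_trait %in% names(assoc)) {
    meta <- run_meta(assoc[[meta_trait]], sel_tab)
    say("meta", "%d SNPs combined, %d significant at %g",
        sum(!is.na(meta$p_meta)),
        sum(meta$p_meta <= thresholds$sig, na.rm = TRUE), thresholds$sig)
  }

  clusters <- list()
  for (tr in traits)
    clusters[[tr]] <- build_clusters(
      assoc[[tr]], p_col = "p_nominal", sig = thresholds$sig,
      weak = thresholds$weak, link_mb = cluster_params$link_mb,
      flank_mb = cluster_params$flank_mb, trait = tr,
      gw_col = "p_genome_wide", gw_threshold = thresholds$gw)
  if (!is.null(meta)) {
    meta_name <- paste0(meta_trait, "_meta")
    meta$trait <- meta_name
    clusters[[meta_name]] <- build_clusters(
      meta, p_col = "p_meta", sig = thresholds$sig, weak = thresholds$weak,
      link_mb = cluster_params$link_mb, flank_mb = cluster_params$flank_mb,
      trait = meta_name, gw_col = "p_meta_genome_wide",
      gw_threshold = thresholds$gw)
  }
  for (nm in names(clusters))
    say("clusters", "%s: %d cluster(s)", nm, nrow(clusters[[nm]]))

  expression <- NULL
  if (run_expression && inherits(cfg, "peck_sim_config")) {
    truth_iv <- if (!is.null(meta) && nrow(clusters[[paste0(meta_trait,
                                                            "_meta")]]) > 0)
      clusters[[paste0(meta_trait, "_meta")]]
    else if (!is.null(truth) && nrow(truth) > 0)
      data.frame(chrom = truth$chrom, start_bp = truth$pos_bp - 1.5e6,
                 end_bp = truth$pos_bp + 1.5e6)
    else NULL
    sim_ex <- simulate_expression(cfg, truth_iv)
    probes <- map_probes_to_clusters(
      sim_ex$probes,
      if (!is.null(meta)) clusters[[paste0(meta_trait, "_meta")]]
      else data.frame(cluster = integer(), chrom = character(),
                      start_bp = numeric(), end_bp = numeric()))
    de_all <- expression_de(sim_ex$line_h, sim_ex$line_l, probes,
                            all_probes = TRUE)
    de_all$p_bh <- stats::p.adjust(de_all$p_nominal, "BH")
    enr <- enrichment_profile(de_all, p_col = "p_bh")
    expression <- list(probes = probes, de = de_all, enrichment = enr,
                       m_in_cluster = attr(probes, "m"))
    say("expression", "%d probes, %d in clusters", nrow(probes),
        attr(probes, "m"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("peckscan")),
    r_version = R.version.string,
    seed = if (inherits(cfg, "peck_sim_config")) cfg$seed else NA,
    config = if (inherits(cfg, "peck_sim_config"))
      cfg[setdiff(names(cfg), "chrom_lengths")] else cfg,
    chrom_lengths = if (inherits(cfg, "peck_sim_config"))
      as.list(cfg$chrom_lengths) else NULL,
    thresholds = thresholds, cluster_params = cluster_params,
    rows = c(list(snps_qc = qc$report$n_retained,
                  individuals = n_individuals(dataset)),
             lapply(assoc, nrow), list(meta = if (is.null(meta)) 0
                                       else nrow(meta))))

  out <- list(dataset = dataset, qc = qc$report, assoc = assoc,
              selection = sel_tab, meta = meta, clusters = clusters,
              expression = expression, ld = ld, truth = truth,
              manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(d, f) utils::write.table(
      d, file.path(out_dir, f), sep = "\t", quote = FALSE,
      row.names = FALSE)
    for (tr in names(assoc)) {
      wt(assoc[[tr]], sprintf("assoc_%s.tsv", tr))
      manh <- data.frame(chrom = assoc[[tr]]$chrom,
                         pos_bp = assoc[[tr]]$pos_bp,
                         neg_log10_p = -log10(pmax(assoc[[tr]]$p_nominal,
                                                   1e-300)))
      wt(manh, sprintf("manhattan_%s.tsv", tr))
    }
    if (!is.null(meta)) {
      wt(meta, sprintf("assoc_%s_meta.tsv", meta_trait))
      wt(data.frame(chrom = meta$chrom, pos_bp = meta$pos_bp,
                    neg_log10_p = -log10(pmax(meta$p_meta, 1e-300))),
         sprintf("manhattan_%s_meta.tsv", meta_trait))
    }
    for (nm in names(clusters)) wt(clusters[[nm]],
                                   sprintf("clusters_%s.tsv", nm))
    if (!is.null(sel_tab)) wt(sel_tab, "selection_pvalues.tsv")
    if (!is.null(ld)) {
      wt(ld$pairs, "ld_pairs.tsv"); wt(ld$profile, "ld_profile.tsv")
    }
    if (!is.null(expression)) {
      wt(expression$de, "expression_de.tsv")
      wt(expression$enrichment, "expression_enrichment.tsv")
    }
    write_qc_report(qc$report, file.path(out_dir, "qc_report"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
  }
  invisible(out)
}
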