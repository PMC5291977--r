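#' Read genotypes from PLINK text PED/MAP or a dosage matrix TSV
#'
#' The PED/MAP dialect is whitespace-delimited: the MAP file has columns
#' chrom, snp_id, cM (ignored), pos_bp; the PED file has the six leading
#' columns FID, IID, PAT, MAT, SEX, PHENO followed by two allele symbols
#' per SNP (`0` = missing). Dosages are oriented to the in-sample minor
#' allele; at an exact 50/50 tie the alphabetically smaller allele is
#' counted, so reading is deterministic.
#'
#' The matrix TSV format has SNPs as rows (`snp_id`, `chrom`, `pos_bp`,
#' then one column per individual holding dosages 0/1/2 or NA).
#'
#' @param path path to the PED file (with a sibling `.map`) or to the
#'   matrix TSV.
#' @param format `"ped_map"` or `"matrix_tsv"`.
#' @param map_path optional explicit MAP path.
#' @return a `peck_dataset` (phenotype slot empty).
#' @export
read_genotypes <- function(path, format = c("ped_map", "matrix_tsv"),
                           map_path = NULL) {
  format <- match.arg(format)
  if (format == "matrix_tsv") return(.read_matrix_tsv(path))
  if (is.null(map_path)) map_path <- sub("\\.ped$", ".map", path)
  map <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "snp_id", "cm", "pos_bp"),
                           colClasses = c("character", "character",
                                          "numeric", "integer"))
  if (anyDuplicated(map$snp_id))
    stop("duplicate snp_id in MAP: ",
         map$snp_id[anyDuplicated(map$snp_id)])
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  want <- 6L + 2L * nrow(map)
  nt <- lengths(toks)
  if (any(nt != want))
    stop(sprintf("malformed PED line %d: %d fields, expected %d",
                 which(nt != want)[1], nt[nt != want][1], want))
  n <- length(toks)
  m <- nrow(map)
  a1 <- matrix("", n, m); a2 <- matrix("", n, m)
  meta <- matrix("", n, 6)
  for (i in seq_len(n)) {
    v <- toks[[i]]
    meta[i, ] <- v[1:6]
    al <- v[-(1:6)]
    a1[i, ] <- al[seq(1, length(al), 2)]
    a2[i, ] <- al[seq(2, length(al), 2)]
  }
  geno <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    s1 <- a1[, j]; s2 <- a2[, j]
    miss <- s1 == "0" | s2 == "0"
    alleles <- sort(unique(c(s1[!miss], s2[!miss])))
    if (length(alleles) > 2)
      stop("more than two alleles at ", map$snp_id[j])
    if (length(alleles) == 0) next
    if (length(alleles) == 1) {
      # monomorphic: the unseen allele is the minor one, dosage 0
      geno[!miss, j] <- 0L
      next
    }
    cnt <- vapply(alleles, function(a)
      sum(s1[!miss] == a) + sum(s2[!miss] == a), numeric(1))
    # count the minor allele; alphabetical tie-break at 50/50
    minor <- alleles[order(cnt, alleles)][1]
    geno[, j] <- (s1 == minor) + (s2 == minor)
    geno[miss, j] <- NA_integer_
  }
  ped <- data.frame(id = meta[, 2], sire = meta[, 3], dam = meta[, 4],
                    hatch = NA_integer_, line = meta[, 1],
                    stringsAsFactors = FALSE)
  rownames(geno) <- ped$id
  new_peck_dataset(map[, c("snp_id", "chrom", "pos_bp")], geno, ped)
}

.read_matrix_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(all(c("snp_id", "chrom", "pos_bp") %in% names(d)))
  if (anyDuplicated(d$snp_id)) stop("duplicate snp_id in matrix TSV")
  ind <- setdiff(names(d), c("snp_id", "chrom", "pos_bp"))
  geno <- t(as.matrix(d[, ind, drop = FALSE]))
  storage.mode(geno) <- "integer"
  ped <- data.frame(id = ind, sire = "0", dam = "0", hatch = NA_integer_,
                    line = NA_character_, stringsAsFactors = FALSE)
  new_peck_dataset(d[, c("snp_id", "chrom", "pos_bp")], geno, ped)
}

#' Write a dataset as PLINK text PED/MAP
#'
#' Alleles are written as A (non-counted) / B (counted); missing
#' dosages as `0 0`.
#'
#' @param dataset a `peck_dataset`.
#' @param prefix output path prefix; writes `<prefix>.ped` and
#'   `<prefix>.map`.
#' @return the prefix, invisibly.
#' @export
write_ped_map <- function(dataset, prefix) {
  map <- dataset$map
  utils::write.table(
    data.frame(map$chrom, map$snp_id, 0, map$pos_bp),
    paste0(prefix, ".map"), sep = " ", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  g <- dataset$geno
  n <- nrow(g)
  code <- c(`0` = "A A", `1` = "A B", `2` = "B B")
  lines <- vapply(seq_len(n), function(i) {
    al <- code[as.character(g[i, ])]
    al[is.na(al)] <- "0 0"
    ped <- dataset$ped[i, ]
    paste(c(ifelse(is.na(ped$line), "0", ped$line), ped$id, ped$sire,
            ped$dam, "0", "-9", al), collapse = " ")
  }, character(1))
  writeLines(lines, paste0(prefix, ".ped"))
  invisible(prefix)
}

#' Write / read the phenotype table
#'
#' TSV with columns `hen_id`, `sire`, `dam`, `hatch`, `FPD`, `APD`,
#' `APR`, `observed_minutes`.
#'
#' @param dataset a `peck_dataset` with phenotypes.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_phenotypes <- function(dataset, path) {
  stopifnot(!is.null(dataset$pheno))
  d <- merge(dataset$ped[, c("id", "sire", "dam", "hatch")],
             dataset$pheno, by = "id", sort = FALSE)
  names(d)[1] <- "hen_id"
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  stopifnot("hen_id" %in% names(d))
  d
}

#' Attach a phenotype table to a dataset
#'
#' Matches on hen id, fills the `hatch` covariate from the table, and
#' keeps sire/dam ids already present in the pedigree unless the table
#' provides them.
#'
#' @param dataset a `peck_dataset`.
#' @param pheno data.frame as returned by [read_phenotypes()].
#' @return the dataset with `pheno` (and pedigree covariates) set.
#' @export
attach_phenotypes <- function(dataset, pheno) {
  i <- match(dataset$ped$id, pheno$hen_id)
  if (anyNA(i)) stop("phenotypes missing for ",
                     sum(is.na(i)), " individual(s)")
  for (col in c("sire", "dam", "hatch"))
    if (col %in% names(pheno)) dataset$ped[[col]] <- pheno[[col]][i]
  keep <- setdiff(names(pheno), c("sire", "dam", "hatch"))
  ph <- pheno[i, keep, drop = FALSE]
  names(ph)[names(ph) == "hen_id"] <- "id"
  rownames(ph) <- NULL
  dataset$pheno <- ph
  dataset
}

#' Write a BED-like probe map and an expression matrix TSV
#'
#' Probe coordinates follow the BED convention (0-based, half-open);
#' SNP map coordinates everywhere else are 1-based. The conversion to a
#' 1-based midpoint for cluster membership happens in
#' [map_probes_to_clusters()].
#'
#' @param probes probe map data.frame (`probe_id`, `chrom`, `start`,
#'   `end`).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_probe_map <- function(probes, path) {
  utils::write.table(probes[, c("chrom", "start", "end", "probe_id")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_probe_map
#' @export
read_probe_map <- function(path) {
  d <- utils::read.table(path, header = FALSE, sep = "\t",
                         stringsAsFactors = FALSE,
                         col.names = c("chrom", "start", "end", "probe_id"))
  d[, c("probe_id", "chrom", "start", "end")]
}

#' @rdname write_probe_map
#' @param mat probe x sample numeric matrix (log2 scale).
#' @export
write_expression <- function(mat, path) {
  d <- data.frame(probe_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_probe_map
#' @export
read_expression <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$probe_id
  m
}

#' Read a selection-signature p-value table
#'
#' TSV keyed by SNP id with columns `snp_id`, `fst`, `p` — either
#' produced by [selection_pvalues()] or supplied from an external scan
#' of the founder lines.
#'
#' @param path TSV path.
#' @return data.frame with `snp_id`, `fst`, `p`.
#' @export
read_selection_table <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  stopifnot(all(c("snp_id", "p") %in% names(d)))
  if (!"fst" %in% names(d)) d$fst <- NA_real_
  d[, c("snp_id", "fst", "p")]
}
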