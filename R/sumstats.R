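# GWAS summary-statistic input, quality control and allele harmonization
# against a target genotype panel.

REQUIRED_SUMSTAT_COLS <- c("chrom", "pos", "effect_allele", "other_allele",
                           "beta", "se", "pval", "eaf", "n")

#' Read GWAS summary statistics from a tab-delimited file
#'
#' Malformed rows (non-positive SE, p-value outside (0, 1], identical or
#' non-ACGT alleles, unparseable numbers) are dropped and counted in the
#' `n_dropped` attribute.
#'
#' @param path Path to a tab-delimited file with a header.
#' @param column_map Named character vector mapping the canonical names
#'   (chrom, pos, effect_allele, other_allele, beta, se, pval, eaf, n) to
#'   the file's column names; identity by default.
#' @return data.frame with the canonical columns; attribute `n_dropped`
#'   holds the number of malformed rows removed.
#' @export
read_sumstats <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop_input("summary-statistics file not found: ", path)
  raw <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  map <- setNames(REQUIRED_SUMSTAT_COLS, REQUIRED_SUMSTAT_COLS)
  if (!is.null(column_map)) map[names(column_map)] <- column_map
  missing_cols <- map[!map %in% names(raw)]
  if (length(missing_cols))
    stop_input("missing required column(s): ",
               paste(sprintf("%s (mapped from %s)", missing_cols,
                             names(missing_cols)), collapse = ", "))
  ss <- raw[, unname(map)]
  names(ss) <- names(map)
  ss$chrom <- as.character(ss$chrom)
  for (cc in c("pos", "beta", "se", "pval", "eaf", "n"))
    ss[[cc]] <- suppressWarnings(as.numeric(ss[[cc]]))
  ss$effect_allele <- toupper(as.character(ss$effect_allele))
  ss$other_allele <- toupper(as.character(ss$other_allele))
  ok <- !is.na(ss$pos) & !is.na(ss$beta) & !is.na(ss$se) & !is.na(ss$pval) &
    ss$se > 0 & ss$pval > 0 & ss$pval <= 1 &
    ss$effect_allele %in% VALID_ALLELES & ss$other_allele %in% VALID_ALLELES &
    ss$effect_allele != ss$other_allele
  ok[is.na(ok)] <- FALSE
  dropped <- sum(!ok)
  if (dropped > 0)
    message("read_sumstats: dropped ", dropped, " malformed row(s)")
  out <- ss[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- dropped
  out
}

#' Quality-control filter for summary statistics
#'
#' Retains variants with minor allele frequency at least `maf_min` in both
#' the GWAS (from `eaf`) and the genotype panel, and panel missingness
#' below `miss_max`.
#'
#' @param sumstats Summary statistics (canonical columns).
#' @param panel_freqs Named numeric vector of panel effect-allele
#'   frequencies, names = variant position keys `chrom:pos`.
#' @param panel_missingness Named numeric vector of panel per-variant
#'   missingness proportions (same names); missing entries treated as 0.
#' @param maf_min MAF cutoff (default 0.01).
#' @param miss_max Panel missingness cutoff (default 0.01; variants with
#'   missingness >= this are removed).
#' @param strict_gwas_maf If TRUE, variants lacking a GWAS `eaf` fail the
#'   GWAS-side MAF test; default lenient (panel-side test governs).
#' @return Filtered sumstats with attribute `report`, a named integer
#'   vector (input, removed_maf, removed_missingness, retained).
#' @export
qc_filter <- function(sumstats, panel_freqs, panel_missingness = NULL,
                      maf_min = 0.01, miss_max = 0.01,
                      strict_gwas_maf = FALSE) {
  key <- pos_key(sumstats$chrom, sumstats$pos)
  pf <- panel_freqs[key]
  pm <- if (is.null(panel_missingness)) rep(0, length(key)) else {
    x <- panel_missingness[key]; x[is.na(x)] <- 0; x
  }
  gwas_maf <- pmin(sumstats$eaf, 1 - sumstats$eaf)
  gwas_ok <- if (strict_gwas_maf) !is.na(gwas_maf) & gwas_maf >= maf_min
             else is.na(gwas_maf) | gwas_maf >= maf_min
  panel_maf <- pmin(pf, 1 - pf)
  panel_ok <- !is.na(panel_maf) & panel_maf >= maf_min
  maf_ok <- gwas_ok & panel_ok
  miss_ok <- pm < miss_max
  keep <- maf_ok & miss_ok
  report <- c(input = nrow(sumstats),
              removed_maf = sum(!maf_ok),
              removed_missingness = sum(maf_ok & !miss_ok),
              retained = sum(keep))
  if (report["retained"] == 0L)
    warning("qc_filter: no variants retained")
  out <- sumstats[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "report") <- report
  out
}

#' Harmonize summary-statistic alleles to a genotype panel
#'
#' Matches variants by (chrom, pos) and aligns the effect allele to the
#' panel's counted allele: exact matches are kept, swapped-allele records
#' have beta negated and eaf complemented (`flipped = TRUE`),
#' strand-ambiguous pairs (A/T, C/G) are removed, and positions absent
#' from the panel or with incompatible allele pairs are removed.
#'
#' @param sumstats Summary statistics (canonical columns).
#' @param panel_variants data.frame with chrom, pos, other_allele,
#'   effect_allele describing the panel's counted-allele coding.
#' @return Harmonized sumstats (panel allele coding, extra `flipped`
#'   column) with attribute `report`: named integer vector (input,
#'   removed_ambiguous, flipped, unmatched, retained) partitioning the
#'   input as input = retained + removed_ambiguous + unmatched.
#' @export
harmonize_alleles <- function(sumstats, panel_variants) {
  pv_key <- pos_key(panel_variants$chrom, panel_variants$pos)
  if (anyDuplicated(pv_key)) {
    dup <- unique(pv_key[duplicated(pv_key)])
    stop_input("panel has duplicate positions with conflicting allele pairs: ",
               paste(head(dup, 5L), collapse = ", "))
  }
  ss_key <- pos_key(sumstats$chrom, sumstats$pos)
  if (anyDuplicated(ss_key)) {
    dd <- ss_key[duplicated(ss_key)]
    conflicting <- unique(dd)
    stop_input("summary statistics contain duplicate positions: ",
               paste(head(conflicting, 5L), collapse = ", "))
  }
  n_input <- nrow(sumstats)
  ambiguous <- is_ambiguous_pair(sumstats$effect_allele, sumstats$other_allele)
  ss <- sumstats[!ambiguous, , drop = FALSE]
  ss_key <- ss_key[!ambiguous]

  idx <- match(ss_key, pv_key)
  found <- !is.na(idx)
  pe <- panel_variants$effect_allele[idx]
  po <- panel_variants$other_allele[idx]
  same <- found & ss$effect_allele == pe & ss$other_allele == po
  swapped <- found & ss$effect_allele == po & ss$other_allele == pe
  matched <- same | swapped

  out <- ss[matched, , drop = FALSE]
  flip <- swapped[matched]
  out$beta[flip] <- -out$beta[flip]
  out$eaf[flip] <- 1 - out$eaf[flip]
  tmp <- out$effect_allele[flip]
  out$effect_allele[flip] <- out$other_allele[flip]
  out$other_allele[flip] <- tmp
  out$flipped <- flip
  rownames(out) <- NULL

  report <- c(input = n_input,
              removed_ambiguous = sum(ambiguous),
              flipped = sum(flip),
              unmatched = sum(!matched),
              retained = nrow(out))
  attr(out, "report") <- report
  out
}

#' Write harmonized summary statistics and report
#'
#' @param sumstats Harmonized summary statistics.
#' @param path Output TSV path.
#' @param report_path Optional JSON path for the harmonization report.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(sumstats, path, report_path = NULL) {
  write.table(sumstats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report_path)) {
    rep <- attr(sumstats, "report")
    jsonlite::write_json(as.list(rep), report_path, auto_unbox = TRUE)
  }
  invisible(path)
}

#' Panel variant frequencies and missingness from a genotype matrix
#'
#' @param genotypes A `genotype_matrix` or dosage matrix with variant-id
#'   columns.
#' @param variants Optional variant table (required for a bare matrix).
#' @return List with `freqs` and `missingness`, both named by `chrom:pos`.
#' @export
panel_stats <- function(genotypes, variants = NULL) {
  if (inherits(genotypes, "genotype_matrix")) {
    X <- genotypes$dosage; variants <- genotypes$variants
  } else X <- genotypes
  if (is.null(variants)) stop_input("variant table required for a bare dosage matrix")
  key <- pos_key(variants$chrom, variants$pos)
  freqs <- setNames(colMeans(X, na.rm = TRUE) / 2, key)
  miss <- setNames(colMeans(is.na(X)), key)
  list(freqs = freqs, missingness = miss)
}
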