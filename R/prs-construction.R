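# Clump-and-threshold PRS construction, additive scoring and
# reference-cohort standardization.

#' Clumping and thresholding parameters
#'
#' Defaults follow standard clump-and-threshold practice: r^2 cutoff 0.1,
#' 1000 kb window, and inclusion p-value thresholds of 5e-8, 1e-5, 1e-2.
#'
#' @param r2_max Squared-correlation cutoff in (0, 1).
#' @param window_kb Distance window in kilobases.
#' @param p_threshold Inclusion p-value threshold in (0, 1].
#' @return List of class `clump_params`.
#' @export
clump_params <- function(r2_max = 0.1, window_kb = 1000, p_threshold = 1e-2) {
  if (r2_max <= 0 || r2_max >= 1) stop_config("r2_max must be in (0, 1)")
  if (window_kb <= 0) stop_config("window_kb must be > 0")
  if (p_threshold <= 0 || p_threshold > 1)
    stop_config("p_threshold must be in (0, 1]")
  structure(list(r2_max = r2_max, window_kb = window_kb,
                 p_threshold = p_threshold), class = "clump_params")
}

#' Greedy LD clumping of summary statistics against a reference panel
#'
#' Among variants with p <= `p_threshold`, repeatedly selects the variant
#' with the smallest p-value (ties broken by chromosome then position),
#' then removes all unselected variants on the same chromosome within
#' `window_kb` whose squared dosage correlation with it in the reference
#' panel exceeds `r2_max`. Monomorphic panel variants have r^2 treated as
#' 0 (they cannot be tagged).
#'
#' @param sumstats Harmonized summary statistics (canonical columns).
#' @param ref_genotypes A `genotype_matrix` (the LD reference panel) whose
#'   variant ids cover the sumstats variants.
#' @param params A [clump_params()].
#' @return Character vector of index-variant ids
#'   (`chrom:pos:other:effect`), ordered by selection.
#' @export
ld_clump <- function(sumstats, ref_genotypes, params = clump_params()) {
  stopifnot(inherits(params, "clump_params"))
  if (nrow(ref_genotypes$dosage) < 2L)
    stop_input("reference panel must contain at least 2 individuals")
  ss <- sumstats[!is.na(sumstats$pval) & sumstats$pval <= params$p_threshold, ,
                 drop = FALSE]
  if (nrow(ss) == 0L) {
    warning("ld_clump: no variants pass p <= ", params$p_threshold)
    return(character(0))
  }
  ids <- variant_id(ss$chrom, ss$pos, ss$other_allele, ss$effect_allele)
  panel_idx <- match(ids, colnames(ref_genotypes$dosage))
  if (anyNA(panel_idx))
    stop_input("sumstats contain variants absent from the reference panel; ",
               "harmonize first (", sum(is.na(panel_idx)), " unmatched)")
  X <- ref_genotypes$dosage[, panel_idx, drop = FALSE]
  sdx <- apply(X, 2L, sd)
  mono <- sdx == 0
  window_bp <- params$window_kb * 1000

  ord <- order(ss$pval, ss$chrom, ss$pos)
  alive <- rep(TRUE, nrow(ss))
  selected <- integer(0)
  for (i in ord) {
    if (!alive[i]) next
    selected <- c(selected, i)
    alive[i] <- FALSE
    cand <- which(alive & ss$chrom == ss$chrom[i] &
                    abs(ss$pos - ss$pos[i]) <= window_bp)
    if (length(cand) == 0L) next
    if (mono[i]) next                         # monomorphic index tags nothing
    cand <- cand[!mono[cand]]
    if (length(cand) == 0L) next
    r <- suppressWarnings(cor(X[, i], X[, cand, drop = FALSE]))
    alive[cand[which(r^2 > params$r2_max)]] <- FALSE
  }
  ids[selected]
}

#' Build a PRS weight table from clumped index variants
#'
#' @param sumstats Harmonized summary statistics.
#' @param index_set Character vector of index-variant ids (from
#'   [ld_clump()]).
#' @param p_threshold Inclusion threshold; index variants with p above it
#'   are excluded.
#' @param source Label recording provenance (GWAS name, method, threshold).
#' @return data.frame of class `weight_table`: variant_id, chrom, pos,
#'   effect_allele, other_allele, weight, source.
#' @export
threshold_weights <- function(sumstats, index_set, p_threshold = 1,
                              source = "C+T") {
  ids <- variant_id(sumstats$chrom, sumstats$pos, sumstats$other_allele,
                    sumstats$effect_allele)
  sel <- ids %in% index_set & !is.na(sumstats$pval) &
    sumstats$pval <= p_threshold
  ss <- sumstats[sel, , drop = FALSE]
  out <- data.frame(variant_id = ids[sel], chrom = ss$chrom, pos = ss$pos,
                    effect_allele = ss$effect_allele,
                    other_allele = ss$other_allele,
                    weight = ss$beta,
                    source = rep_len(source, sum(sel)),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$variant_id))
    stop_input("duplicate variant ids in weight table")
  if (any(!is.finite(out$weight)))
    stop_input("non-finite weights in weight table")
  rownames(out) <- NULL
  class(out) <- c("weight_table", "data.frame")
  out
}

#' Score individuals with a PRS weight table
#'
#' Additive scoring: PRS_j = sum_v weight_v * dosage_jv. Missing dosages
#' are imputed as twice the panel effect-allele frequency (default) or the
#' variant is scored as zero contribution for that individual
#' (`missing_policy = "zero"`). Weights for variants absent from the
#' genotypes are dropped with a count (or an error in strict mode).
#'
#' @param genotypes A `genotype_matrix` or dosage matrix with variant-id
#'   columns (values in \[0, 2\] or NA).
#' @param weights A `weight_table`.
#' @param missing_policy `"impute_eaf"` (default) or `"zero"`.
#' @param strict Error (rather than drop) on weights absent from the
#'   genotypes.
#' @return Named numeric vector of raw scores; attribute `n_dropped`
#'   counts dropped weights.
#' @export
score_prs <- function(genotypes, weights,
                      missing_policy = c("impute_eaf", "zero"),
                      strict = FALSE) {
  missing_policy <- match.arg(missing_policy)
  X <- if (inherits(genotypes, "genotype_matrix")) genotypes$dosage else genotypes
  idx <- match(weights$variant_id, colnames(X))
  absent <- is.na(idx)
  if (any(absent)) {
    if (strict)
      stop_input(sum(absent), " weight variant(s) absent from genotypes, e.g. ",
                 weights$variant_id[which(absent)[1L]])
    idx <- idx[!absent]
  }
  w <- weights$weight[!absent]
  Xs <- X[, idx, drop = FALSE]
  if (anyNA(Xs)) {
    if (missing_policy == "impute_eaf") {
      fill <- colMeans(Xs, na.rm = TRUE)      # = 2 x panel EAF
      for (j in which(colSums(is.na(Xs)) > 0L))
        Xs[is.na(Xs[, j]), j] <- fill[j]
    } else {
      Xs[is.na(Xs)] <- 0
    }
  }
  score <- drop(Xs %*% w)
  names(score) <- rownames(X)
  attr(score, "n_dropped") <- sum(absent)
  score
}

#' Standardize a raw PRS to a reference cohort
#'
#' Centers and scales so the reference cohort has mean 0 and variance 1;
#' external cohorts are transformed with the stored reference constants.
#'
#' @param raw_prs Named numeric vector of raw scores.
#' @param reference Either a numeric vector of reference-cohort raw scores
#'   (constants are estimated from it) or a list with `ref_mean`,
#'   `ref_sd` (and optionally `ref_id`).
#' @param ref_id Reference-cohort label stored with the constants.
#' @return Object of class `std_prs`: list with `score` (named numeric),
#'   `ref_mean`, `ref_sd`, `ref_id`.
#' @export
standardize_prs <- function(raw_prs, reference = raw_prs, ref_id = "reference") {
  if (is.list(reference)) {
    ref_mean <- reference$ref_mean; ref_sd <- reference$ref_sd
    ref_id <- reference$ref_id %||% ref_id
  } else {
    ref_mean <- mean(reference); ref_sd <- sd(reference)
  }
  if (!is.finite(ref_sd) || ref_sd <= 0)
    stop_numeric("reference PRS has zero (or undefined) SD; cannot standardize")
  structure(list(score = (raw_prs - ref_mean) / ref_sd,
                 ref_mean = ref_mean, ref_sd = ref_sd, ref_id = ref_id),
            class = "std_prs")
}

#' @export
print.std_prs <- function(x, ...) {
  cat("standardized PRS: n =", length(x$score),
      sprintf("(ref %s: mean %.4g, sd %.4g)\n", x$ref_id, x$ref_mean, x$ref_sd))
  invisible(x)
}

#' Write / read a PRS weight table
#'
#' Four-column TSV (variant_id, effect_allele, weight, source); the
#' variant id `chrom:pos:other:effect` carries the position and allele
#' pair. `read_weight_table` also accepts 3-column PLINK `--score` files
#' (variant id, effect allele, weight, no header).
#'
#' @param weights A `weight_table`.
#' @param path File path.
#' @return `path` (write) or a `weight_table` (read).
#' @export
write_weight_table <- function(weights, path) {
  write.table(weights[, c("variant_id", "effect_allele", "weight", "source")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weight_table
#' @param source Source label applied when the file lacks one.
#' @export
read_weight_table <- function(path, source = "external") {
  if (!file.exists(path)) stop_input("weight table not found: ", path)
  first <- readLines(path, n = 1L)
  has_header <- grepl("variant_id", first, fixed = TRUE)
  tab <- read.delim(path, header = has_header, stringsAsFactors = FALSE)
  if (!has_header) {
    if (ncol(tab) < 3L) stop_input("PLINK score file needs 3 columns")
    names(tab)[1:3] <- c("variant_id", "effect_allele", "weight")
  }
  if (!"source" %in% names(tab)) tab$source <- source
  parts <- strsplit(tab$variant_id, ":", fixed = TRUE)
  if (any(lengths(parts) != 4L))
    stop_input("variant ids must be chrom:pos:other:effect")
  out <- data.frame(variant_id = tab$variant_id,
                    chrom = vapply(parts, `[[`, character(1), 1L),
                    pos = as.numeric(vapply(parts, `[[`, character(1), 2L)),
                    effect_allele = toupper(tab$effect_allele),
                    other_allele = vapply(parts, `[[`, character(1), 3L),
                    weight = as.numeric(tab$weight), source = tab$source,
                    stringsAsFactors = FALSE)
  # ids carry other:effect; trust the explicit effect_allele column and
  # recover the other allele from the id pair
  id_eff <- vapply(parts, `[[`, character(1), 4L)
  swap <- out$effect_allele != id_eff
  out$other_allele[swap] <- id_eff[swap]
  if (any(!is.finite(out$weight))) stop_input("non-finite weights in ", path)
  class(out) <- c("weight_table", "data.frame")
  out
}
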