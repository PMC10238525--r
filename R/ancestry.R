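# Ancestry diagnostics: ancestry-specific allele frequencies from global
# admixture proportions, >= 80%-ancestry grouping, and the effect-size vs
# frequency profile.

#' Drop one ancestry and rescale admixture proportions
#'
#' Rows whose dropped-ancestry fraction is at most `max_dropped` have the
#' column removed and the remainder renormalized to sum to 1; rows above
#' the cap are flagged excluded (their rescaled proportions are NA).
#'
#' @param proportions n x K matrix or data.frame of admixture proportions,
#'   columns named by ancestry; rows sum to 1.
#' @param drop_label Ancestry column to drop.
#' @param max_dropped Maximum tolerated fraction of the dropped ancestry
#'   (default 0.05).
#' @return List with `proportions` (n x (K-1) matrix, NA rows for excluded
#'   individuals) and `excluded` (logical vector).
#' @export
rescale_ancestry_proportions <- function(proportions, drop_label,
                                         max_dropped = 0.05) {
  Q <- as.matrix(proportions)
  if (!drop_label %in% colnames(Q))
    stop_input("ancestry '", drop_label, "' not found; columns: ",
               paste(colnames(Q), collapse = ", "))
  if (any(abs(rowSums(Q) - 1) > 1e-8))
    stop_input("proportion rows must sum to 1")
  dropped <- Q[, drop_label]
  excluded <- dropped > max_dropped
  R <- Q[, setdiff(colnames(Q), drop_label), drop = FALSE]
  R <- R / rowSums(R)
  R[excluded, ] <- NA_real_
  list(proportions = R, excluded = excluded)
}

#' Estimate ancestry-specific allele frequencies
#'
#' Per-variant box-constrained least squares under the admixture model
#' E\[dosage_i\] = 2 sum_k q_ik p_k: minimize ||d - 2 Q p||^2 subject to
#' 0 <= p_k <= 1. The unconstrained normal-equation solution is used when
#' it already satisfies the box; otherwise L-BFGS-B with analytic
#' gradient. A simplification of ancestry-specific frequency estimators
#' that use local ancestry; unbiased when the global-proportion model
#' holds.
#'
#' @param dosages n x m dosage matrix (columns named by variant).
#' @param ancestry_proportions n x K matrix, columns named by ancestry.
#' @return data.frame of class `ancestry_freq_table`: variant id, one
#'   `freq_<ancestry>` column per ancestry, and `resid_norm` (root mean
#'   squared residual of the fit).
#' @export
estimate_ancestry_freqs <- function(dosages, ancestry_proportions) {
  Q <- as.matrix(ancestry_proportions)
  X <- as.matrix(dosages)
  K <- ncol(Q); n <- nrow(Q)
  if (nrow(X) != n) stop_input("dosages and proportions cover different n")
  if (n < K + 1L) stop_input("need at least K+1 = ", K + 1L, " individuals")
  if (qr(Q)$rank < K) {
    stop_numeric("ancestry design is collinear; ancestries not jointly ",
                 "identifiable: ", paste(colnames(Q), collapse = ", "))
  }
  A <- 4 * crossprod(Q)                     # Hessian of ||d - 2Qp||^2
  Achol <- chol(A)
  Qt2 <- 2 * t(Q)
  p_hat <- matrix(NA_real_, ncol(X), K,
                  dimnames = list(colnames(X), colnames(Q)))
  rn <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) {
    d <- X[, j]
    b <- Qt2 %*% d
    p0 <- drop(backsolve(Achol, forwardsolve(t(Achol), b)))
    if (all(p0 >= 0 & p0 <= 1)) {
      p <- p0
    } else {
      obj <- function(p) sum((d - drop(2 * Q %*% p))^2)
      grad <- function(p) drop(A %*% p - b)
      p <- optim(pmin(pmax(p0, 0), 1), obj, grad, method = "L-BFGS-B",
                 lower = rep(0, K), upper = rep(1, K))$par
    }
    p_hat[j, ] <- p
    rn[j] <- sqrt(mean((d - drop(2 * Q %*% p))^2))
  }
  out <- data.frame(variant_id = colnames(X) %||% seq_len(ncol(X)),
                    p_hat, resid_norm = rn, stringsAsFactors = FALSE,
                    row.names = NULL)
  names(out)[1L + seq_len(K)] <- paste0("freq_", colnames(Q))
  class(out) <- c("ancestry_freq_table", "data.frame")
  out
}

#' Assign individuals to majority-ancestry groups
#'
#' Labels an individual with an ancestry when at least `cutoff` (default
#' 80%) of their alleles are attributed to it; otherwise unassigned (NA).
#'
#' @param proportions n x K matrix, columns named by ancestry.
#' @param cutoff Inclusive proportion cutoff (default 0.8).
#' @return Character vector of ancestry labels (NA = unassigned).
#' @export
assign_ancestry_group <- function(proportions, cutoff = 0.8) {
  Q <- as.matrix(proportions)
  top <- max.col(Q, ties.method = "first")
  val <- Q[cbind(seq_len(nrow(Q)), top)]
  ifelse(val >= cutoff, colnames(Q)[top], NA_character_)
}

#' Effect-size versus ancestry-specific-frequency profile
#'
#' For clumped variants with p-value below `p_max`, bins each ancestry's
#' estimated allele frequencies into deciles and summarizes the absolute
#' effect size per bin (median and IQR). The matched-ancestry profile of a
#' GWAS typically falls from both frequency extremes toward 0.5 (rare
#' variants carry larger effects); mismatched ancestries flatten it.
#'
#' @param sumstats Summary statistics of the clumped variants (canonical
#'   columns).
#' @param ancestry_freq_table Output of [estimate_ancestry_freqs()]
#'   covering the same variants (matched by variant id).
#' @param p_max P-value cap (default 0.01).
#' @param n_bins Number of frequency bins (default 10, i.e. deciles).
#' @return data.frame: ancestry, bin, freq_lo, freq_hi, n,
#'   median_abs_beta, iqr_abs_beta. Empty bins are absent (reported as
#'   missing, not zero).
#' @export
effect_frequency_profile <- function(sumstats, ancestry_freq_table,
                                     p_max = 0.01, n_bins = 10L) {
  ss <- sumstats[!is.na(sumstats$pval) & sumstats$pval < p_max, , drop = FALSE]
  ids <- variant_id(ss$chrom, ss$pos, ss$other_allele, ss$effect_allele)
  ft <- ancestry_freq_table[match(ids, ancestry_freq_table$variant_id), ,
                            drop = FALSE]
  anc_cols <- grep("^freq_", names(ft), value = TRUE)
  out <- list()
  for (ac in anc_cols) {
    f <- ft[[ac]]
    ok <- !is.na(f) & !is.na(ss$beta)
    if (!any(ok)) next
    br <- unique(quantile(f[ok], probs = seq(0, 1, length.out = n_bins + 1L),
                          names = FALSE))
    if (length(br) < 2L) br <- c(br - 1e-9, br + 1e-9)
    bin <- cut(f[ok], breaks = br, include.lowest = TRUE)
    ab <- abs(ss$beta[ok])
    med <- tapply(ab, bin, median)
    iqr <- tapply(ab, bin, IQR)
    cnt <- tapply(ab, bin, length)
    keep <- !is.na(med)
    lo <- br[-length(br)][keep]; hi <- br[-1L][keep]
    out[[ac]] <- data.frame(ancestry = sub("^freq_", "", ac),
                            bin = which(keep), freq_lo = lo, freq_hi = hi,
                            n = as.integer(cnt[keep]),
                            median_abs_beta = as.numeric(med[keep]),
                            iqr_abs_beta = as.numeric(iqr[keep]),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
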