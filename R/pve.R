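# Percent variance explained (PVE) with percentile-bootstrap confidence
# intervals and stratified evaluation.
#
# PVE = (1 - sigma2_prs / sigma2_null) * 100, where sigma2_prs is the
# residual variance of the covariates + PRS model and sigma2_null that of
# the covariates-only model, both fit on unrelated individuals.

# Residual variance (df-adjusted) of y on design X via least squares.
resid_variance <- function(X, y) {
  fit <- .lm.fit(X, y)
  if (fit$rank < ncol(X)) stop_numeric("singular design in PVE model")
  sum(fit$residuals^2) / (length(y) - ncol(X))
}

pve_from_designs <- function(X_null, X_full, y, variance_groups = NULL) {
  if (is.null(variance_groups)) {
    s2_null <- resid_variance(X_null, y)
    s2_prs <- resid_variance(X_full, y)
  } else {
    s2_null <- pooled_group_variance(X_null, y, variance_groups)
    s2_prs <- pooled_group_variance(X_full, y, variance_groups)
  }
  list(sigma2_null = s2_null, sigma2_prs = s2_prs,
       pve = (1 - s2_prs / s2_null) * 100)
}

# FGLS residual variances per group pooled by degrees-of-freedom
# weighting: pooled sigma2 = sum_g df_g s2_g / sum_g df_g with model df
# allocated to groups proportionally to size.
pooled_group_variance <- function(X, y, g, tol = 1e-8, max_iter = 50L) {
  n <- length(y); p <- ncol(X)
  g <- factor(g)
  sig2 <- rep(1, nlevels(g))
  w <- rep(1, n)
  for (it in seq_len(max_iter)) {
    fit <- .lm.fit(X * sqrt(w), y * sqrt(w))
    if (fit$rank < ncol(X)) stop_numeric("singular design in PVE model")
    r <- y - drop(X %*% fit$coefficients)
    new_sig2 <- as.numeric(tapply(r^2, g, mean))
    rel <- max(abs(new_sig2 - sig2) / new_sig2)
    sig2 <- new_sig2
    w <- 1 / sig2[as.integer(g)]
    if (rel < tol) break
  }
  ng <- as.numeric(tabulate(g))
  # per-group df-adjusted variances RSS_g / df_g, pooled with df weights:
  # sum_g df_g * (RSS_g/df_g) / sum_g df_g = sum_g RSS_g / (n - p)
  sum(sig2 * ng) / (n - p)
}

#' Percent variance explained by a PRS
#'
#' Fits the covariates-only and covariates + PRS linear models on the
#' unrelated subset and returns PVE = (1 - sigma2_prs/sigma2_null) x 100.
#' Negative values are reported as-is. With
#' `variance_handling = "pooled"`, per-group FGLS residual variances are
#' pooled by degrees-of-freedom weighting before entering the ratio.
#'
#' @param data data.frame with outcome, PRS, covariates, `id` and
#'   (optionally) variance-group columns.
#' @param outcome,prs,covariates Column names as in [fit_association()].
#' @param unrelated_ids Character vector of ids to restrict to (from
#'   [select_unrelated()]); NULL = all rows.
#' @param group_intercepts Optional group-intercept column.
#' @param variance_handling `"homogeneous"` (default) or `"pooled"`.
#' @param variance_groups Variance-group column (required for pooled).
#' @return Object of class `pve_result`: list with sigma2_null,
#'   sigma2_prs, pve, n, stratum (NA here; filled by
#'   [stratified_evaluation()]).
#' @export
compute_pve <- function(data, outcome, prs, covariates = character(0),
                        unrelated_ids = NULL, group_intercepts = NULL,
                        variance_handling = c("homogeneous", "pooled"),
                        variance_groups = NULL) {
  variance_handling <- match.arg(variance_handling)
  if (!is.null(unrelated_ids)) {
    if (is.null(data$id)) stop_input("data needs an id column to subset on")
    data <- data[data$id %in% unrelated_ids, , drop = FALSE]
  }
  used <- c(outcome, prs, covariates, group_intercepts, variance_groups)
  data <- data[complete.cases(data[, used, drop = FALSE]), , drop = FALSE]
  y <- data[[outcome]]
  X_full <- build_design(data, prs, covariates, group_intercepts)
  X_null <- X_full[, setdiff(colnames(X_full), "prs"), drop = FALSE]
  if (nrow(X_full) < ncol(X_full) + 2L)
    stop_input("insufficient data: ", nrow(X_full), " unrelated individuals for ",
               ncol(X_full), " parameters")
  vg <- if (variance_handling == "pooled") {
    if (is.null(variance_groups)) stop_input("pooled handling requires variance_groups")
    factor(data[[variance_groups]])
  } else NULL
  res <- pve_from_designs(X_null, X_full, y, vg)
  structure(c(res, list(n = nrow(X_full), stratum = NA_character_)),
            class = "pve_result")
}

#' @export
print.pve_result <- function(x, ...) {
  cat(sprintf("PVE = %.3f%% (sigma2_null %.4g, sigma2_prs %.4g, n = %d)",
              x$pve, x$sigma2_null, x$sigma2_prs, x$n))
  if (!is.null(x$ci_lo)) cat(sprintf(" [95%% CI %.3f, %.3f]", x$ci_lo, x$ci_hi))
  cat("\n")
  invisible(x)
}

#' Percentile-bootstrap confidence interval for PVE
#'
#' Resamples individuals (rows of the fixed unrelated subset) with
#' replacement `n_boot` times, recomputes PVE for each replicate, and
#' returns the 2.5 and 97.5 empirical percentiles. Replicates with a
#' singular design are redrawn (at most 10 retries each).
#'
#' @inheritParams compute_pve
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Integer seed (mandatory for reproducibility).
#' @param conf Confidence level (default 0.95).
#' @return List with `ci_lo`, `ci_hi`, `pve` (point estimate), `n_boot`,
#'   `replicates` (the bootstrap PVE draws).
#' @export
bootstrap_pve_ci <- function(data, outcome, prs, covariates = character(0),
                             unrelated_ids = NULL, group_intercepts = NULL,
                             n_boot = 1000L, seed = 1L, conf = 0.95) {
  if (!is.null(unrelated_ids)) {
    if (is.null(data$id)) stop_input("data needs an id column to subset on")
    data <- data[data$id %in% unrelated_ids, , drop = FALSE]
  }
  used <- c(outcome, prs, covariates, group_intercepts)
  data <- data[complete.cases(data[, used, drop = FALSE]), , drop = FALSE]
  y <- data[[outcome]]
  X_full <- build_design(data, prs, covariates, group_intercepts)
  X_null <- X_full[, setdiff(colnames(X_full), "prs"), drop = FALSE]
  n <- length(y)
  point <- pve_from_designs(X_null, X_full, y)$pve

  set.seed(seed)
  reps <- numeric(n_boot)
  n_redrawn <- 0L
  for (b in seq_len(n_boot)) {
    ok <- FALSE
    for (try in seq_len(10L)) {
      idx <- sample.int(n, n, replace = TRUE)
      val <- tryCatch(pve_from_designs(X_null[idx, , drop = FALSE],
                                       X_full[idx, , drop = FALSE],
                                       y[idx])$pve,
                      multiprs_numeric_error = function(e) NA_real_)
      if (!is.na(val)) { ok <- TRUE; break }
      n_redrawn <- n_redrawn + 1L
    }
    if (!ok) stop_numeric("bootstrap replicate ", b,
                          " singular after 10 redraws")
    reps[b] <- val
  }
  alpha <- (1 - conf) / 2
  ci <- as.numeric(quantile(reps, c(alpha, 1 - alpha), names = FALSE))
  if (n_redrawn > 0L)
    message("bootstrap_pve_ci: redrew ", n_redrawn, " singular replicate(s)")
  list(ci_lo = ci[1L], ci_hi = ci[2L], pve = point, n_boot = n_boot,
       replicates = reps)
}

#' Stratified association and PVE evaluation
#'
#' Runs [fit_association()] and [compute_pve()] within each level of each
#' stratifying column (e.g. age band, sex, obesity, medication use) and
#' returns one row per stratum. Strata below `min_n` individuals are
#' skipped with a warning. A `"all"` pseudo-stratum covering the whole
#' cohort is prepended.
#'
#' @param data Prepared data.frame (see [assign_strata()]).
#' @param outcome,prs,covariates,group_intercepts As in
#'   [fit_association()].
#' @param strata Character vector of stratum-label column names.
#' @param unrelated_ids Optional ids for the PVE computations.
#' @param min_n Minimum stratum size (default 50).
#' @param n_boot If > 0, adds percentile-bootstrap CI columns.
#' @param seed Bootstrap seed.
#' @param prs_label Label written into the output table.
#' @return data.frame: stratum, level, prs_label, n, beta, se, pval, pve,
#'   sigma2_null, sigma2_prs (and ci_lo, ci_hi when `n_boot > 0`).
#' @export
stratified_evaluation <- function(data, outcome, prs,
                                  covariates = character(0),
                                  group_intercepts = NULL,
                                  strata = character(0),
                                  unrelated_ids = NULL, min_n = 50L,
                                  n_boot = 0L, seed = 1L,
                                  prs_label = prs) {
  run_one <- function(rows, stratum, level) {
    df <- data[rows, , drop = FALSE]
    # a covariate constant within the stratum (e.g. sex inside a sex
    # stratum) would make the design singular; drop it here
    covariates <- covariates[vapply(covariates, function(cv)
      length(unique(df[[cv]][!is.na(df[[cv]])])) > 1L, logical(1))]
    fit <- fit_association(df, outcome, prs, covariates,
                           group_intercepts = group_intercepts)
    pve <- compute_pve(df, outcome, prs, covariates,
                       unrelated_ids = unrelated_ids,
                       group_intercepts = group_intercepts)
    row <- data.frame(stratum = stratum, level = level,
                      prs_label = prs_label, n = fit$n,
                      beta = fit$beta_prs, se = fit$se, pval = fit$pval,
                      pve = pve$pve, sigma2_null = pve$sigma2_null,
                      sigma2_prs = pve$sigma2_prs,
                      stringsAsFactors = FALSE)
    if (n_boot > 0L) {
      ci <- bootstrap_pve_ci(df, outcome, prs, covariates,
                             unrelated_ids = unrelated_ids,
                             group_intercepts = group_intercepts,
                             n_boot = n_boot,
                             seed = derive_seed(seed, nrow(out) + 1L))
      row$ci_lo <- ci$ci_lo; row$ci_hi <- ci$ci_hi
    }
    row
  }
  out <- data.frame()
  out <- rbind(out, run_one(seq_len(nrow(data)), "all", "all"))
  for (st in strata) {
    lv <- unique(data[[st]])
    lv <- lv[!is.na(lv)]
    for (l in sort(as.character(lv))) {
      rows <- which(!is.na(data[[st]]) & as.character(data[[st]]) == l)
      if (length(rows) < min_n) {
        warning("stratum ", st, "=", l, " below min_n (", length(rows),
                " < ", min_n, "); skipped")
        next
      }
      out <- rbind(out, run_one(rows, st, l))
    }
  }
  rownames(out) <- NULL
  out
}
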