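# PRS-trait association models: group intercepts, heterogeneous residual
# variances (FGLS), optional kinship random effect; Wald inference.

# Build the design matrix: group intercepts (factor expansion, no
# reference level collapsing into a separate intercept) or a plain
# intercept, then covariates, then the PRS as the last column.
build_design <- function(data, prs, covariates, group_intercepts) {
  n <- nrow(data)
  if (!is.null(group_intercepts) &&
      nlevels(factor(data[[group_intercepts]])) > 1L) {
    g <- factor(data[[group_intercepts]])
    X0 <- model.matrix(~ g)
    colnames(X0) <- c("(Intercept)", paste0("group_", levels(g)[-1]))
  } else {
    X0 <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  }
  if (length(covariates)) {
    Xc <- model.matrix(as.formula(paste("~", paste(covariates, collapse = "+"))),
                       data = data)[, -1L, drop = FALSE]
    X0 <- cbind(X0, Xc)
  }
  if (!is.null(prs)) {
    pr <- if (inherits(data[[prs]], "std_prs")) data[[prs]]$score else data[[prs]]
    X0 <- cbind(X0, prs = pr)
  }
  X0
}

wls_fit <- function(X, y, w) {
  sw <- sqrt(w)
  fit <- lm.fit(X * sw, y * sw)
  if (fit$rank < ncol(X))
    stop_numeric("singular design; collinear column(s): ",
                 paste(colnames(X)[is.na(fit$coefficients)], collapse = ", "))
  fit
}

#' Fit a PRS-trait association model
#'
#' Linear model of the trait on group-specific intercepts, covariates and
#' the PRS. With `variance_groups`, residual variances differ by group and
#' the model is fit by feasible generalized least squares: iterate
#' weighted least squares and per-group variance re-estimation until the
#' maximum relative change in group variances is below `tol` (or
#' `max_iter`). With a kinship matrix, a two-variance-component model
#' y = Xb + g + e with g ~ N(0, sigma2_g * 2K) and homogeneous residual e
#' is fit by profiling the likelihood over h = sigma2_g / sigma2_total via
#' a log-spaced grid refined by golden-section search on eigen-rotated
#' data. The PRS Wald test is a two-sided 1-df normal-reference test.
#'
#' @param data data.frame with outcome, PRS and covariate columns.
#' @param outcome Outcome column name.
#' @param prs PRS column name (coefficient reported as `beta_prs`).
#' @param covariates Character vector of covariate column names.
#' @param group_intercepts Optional column name for group-specific
#'   intercepts.
#' @param variance_groups Optional column name defining residual-variance
#'   groups (FGLS path; ignored when `kinship` is given).
#' @param kinship Optional n x n kinship matrix aligned to `data$id`.
#' @param fixed_group_variances Optional named numeric vector of known
#'   residual variances per variance group; skips FGLS iteration and fits
#'   one weighted least squares at these variances.
#' @param tol,max_iter FGLS convergence controls.
#' @return Object of class `association_fit`: beta_prs, se, pval,
#'   coefficients, group_variances (or sigma2_g / sigma2_e), n, n_dropped,
#'   converged, iterations.
#' @export
fit_association <- function(data, outcome, prs, covariates = character(0),
                            group_intercepts = NULL, variance_groups = NULL,
                            kinship = NULL, fixed_group_variances = NULL,
                            tol = 1e-8, max_iter = 50L) {
  used <- c(outcome, prs, covariates, group_intercepts, variance_groups)
  cc <- complete.cases(data[, used, drop = FALSE])
  n_dropped <- sum(!cc)
  df <- data[cc, , drop = FALSE]
  y <- df[[outcome]]
  X <- build_design(df, prs, covariates, group_intercepts)
  n <- nrow(X); p <- ncol(X)
  if (n <= p + 1L) stop_input("too few complete cases (", n, ") for ", p,
                              " parameters")

  if (!is.null(kinship)) {
    res <- fit_kinship_model(X, y, df$id, kinship)
  } else if (!is.null(variance_groups) && !is.null(fixed_group_variances)) {
    g <- factor(df[[variance_groups]])
    if (!all(levels(g) %in% names(fixed_group_variances)))
      stop_input("fixed_group_variances must be named by all variance groups")
    w <- 1 / fixed_group_variances[as.character(g)]
    fit <- wls_fit(X, y, w)
    XtWX_inv <- chol2inv(chol(crossprod(X * sqrt(w))))
    res <- list(coefficients = setNames(fit$coefficients, colnames(X)),
                se = setNames(sqrt(diag(XtWX_inv)), colnames(X)),
                group_variances = fixed_group_variances[levels(g)],
                converged = TRUE, iterations = 1L)
  } else if (!is.null(variance_groups)) {
    g <- factor(df[[variance_groups]])
    w <- rep(1, n)
    sig2 <- rep(1, nlevels(g))
    converged <- FALSE; it <- 0L
    repeat {
      it <- it + 1L
      fit <- wls_fit(X, y, w)
      r <- y - drop(X %*% fit$coefficients)
      new_sig2 <- as.numeric(tapply(r^2, g, mean))
      if (any(new_sig2 <= 0)) stop_numeric("a variance group collapsed to zero")
      rel <- max(abs(new_sig2 - sig2) / new_sig2)
      sig2 <- new_sig2
      w <- 1 / sig2[as.integer(g)]
      if (rel < tol) { converged <- TRUE; break }
      if (it >= max_iter) break
    }
    if (!converged)
      stop_numeric("FGLS did not converge in ", max_iter,
                   " iterations (last relative change ", format(rel), ")")
    fit <- wls_fit(X, y, w)
    XtWX_inv <- chol2inv(chol(crossprod(X * sqrt(w))))
    se_all <- sqrt(diag(XtWX_inv)) * sqrt(n / (n - p))
    res <- list(coefficients = setNames(fit$coefficients, colnames(X)),
                se = setNames(se_all, colnames(X)),
                group_variances = setNames(sig2 * n / (n - p), levels(g)),
                converged = TRUE, iterations = it)
  } else {
    fit <- lm.fit(X, y)
    if (fit$rank < ncol(X))
      stop_numeric("singular design; collinear column(s): ",
                   paste(colnames(X)[is.na(fit$coefficients)], collapse = ", "))
    r <- fit$residuals
    s2 <- sum(r^2) / (n - p)
    XtX_inv <- chol2inv(chol(crossprod(X)))
    se_all <- sqrt(diag(XtX_inv) * s2)
    res <- list(coefficients = setNames(fit$coefficients, colnames(X)),
                se = setNames(se_all, colnames(X)),
                group_variances = c(all = s2),
                converged = TRUE, iterations = 1L)
  }
  b <- res$coefficients["prs"]
  se <- res$se["prs"]
  pval <- 2 * pnorm(-abs(b / se))
  structure(c(list(beta_prs = unname(b), se = unname(se),
                   pval = unname(max(pval, .Machine$double.xmin)),
                   n = n, n_dropped = n_dropped), res),
            class = "association_fit")
}

#' @export
print.association_fit <- function(x, ...) {
  cat(sprintf("association fit (n = %d): beta_prs = %.4g (se %.4g, p = %.3g)\n",
              x$n, x$beta_prs, x$se, x$pval))
  invisible(x)
}

# Two-variance-component model via eigendecomposition of 2K: rotate by the
# eigenvectors so the covariance is diagonal, profile the REML-type
# likelihood over h = sigma2_g/sigma2_tot on a grid refined by
# golden-section search.
fit_kinship_model <- function(X, y, ids, kinship) {
  if (is.null(ids)) stop_input("kinship model requires an id column in data")
  if (!all(ids %in% rownames(kinship)))
    stop_input("kinship matrix does not cover all individuals")
  K2 <- 2 * kinship[ids, ids]
  eg <- tryCatch(eigen(K2, symmetric = TRUE),
                 error = function(e) stop_numeric("kinship eigendecomposition failed"))
  lam <- eg$values
  if (min(lam) < -1e-8 * max(abs(lam)))
    stop_numeric("kinship matrix is not positive semi-definite (min eigenvalue ",
                 format(min(lam)), ")")
  lam <- pmax(lam, 0)
  U <- eg$vectors
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)
  n <- length(yt); p <- ncol(Xt)

  nll <- function(h) {
    d <- h * lam + (1 - h)                 # V = sigma2_tot * diag(d)
    w <- 1 / d
    fit <- lm.fit(Xt * sqrt(w), yt * sqrt(w))
    rss <- sum(fit$residuals^2)
    s2 <- rss / (n - p)
    (n - p) * log(s2) + sum(log(d))        # profiled (restricted-type) deviance
  }
  hs <- unique(c(0, 10^seq(-4, -0.05, length.out = 20), 0.99))
  vals <- vapply(hs, nll, numeric(1))
  i <- which.min(vals)
  lo <- hs[max(i - 1L, 1L)]; hi <- hs[min(i + 1L, length(hs))]
  opt <- optimize(nll, c(lo, hi), tol = 1e-8)
  h <- if (opt$objective < vals[i]) opt$minimum else hs[i]

  d <- h * lam + (1 - h)
  w <- 1 / d
  fit <- wls_fit(Xt, yt, w)
  rss <- sum((sqrt(w) * (yt - drop(Xt %*% fit$coefficients)))^2)
  s2_tot <- rss / (n - p)
  XtWX_inv <- chol2inv(chol(crossprod(Xt * sqrt(w))))
  se_all <- sqrt(diag(XtWX_inv) * s2_tot)
  list(coefficients = setNames(fit$coefficients, colnames(X)),
       se = setNames(se_all, colnames(X)),
       sigma2_g = h * s2_tot, sigma2_e = (1 - h) * s2_tot,
       heritability_ratio = h,
       group_variances = c(all = (1 - h) * s2_tot),
       converged = TRUE, iterations = 1L)
}

#' Rank-based AUC (Mann-Whitney with midranks)
#'
#' Probability that a randomly chosen case outscores a randomly chosen
#' control, counting ties as one half.
#'
#' @param outcome Binary vector (logical or 0/1).
#' @param score Numeric score.
#' @return AUC in \[0, 1\].
#' @export
compute_auc <- function(outcome, score) {
  ok <- !is.na(outcome) & !is.na(score)
  y <- as.integer(outcome[ok]); s <- score[ok]
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L)
    stop_input("AUC undefined: both outcome classes must be present")
  r <- rank(s, ties.method = "average")
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
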