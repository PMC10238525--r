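# Unweighted and regression-weighted sums of standardized component PRSs,
# and cross-dataset scale / scale+match harmonization.

# Coerce a components argument (list of std_prs / named list of numeric /
# matrix / data.frame) to an n x p numeric matrix with aligned ids.
components_matrix <- function(components) {
  if (is.matrix(components) || is.data.frame(components))
    return(as.matrix(components))
  stopifnot(is.list(components), length(components) >= 1L)
  cols <- lapply(components, function(x) if (inherits(x, "std_prs")) x$score else x)
  ids <- lapply(cols, names)
  if (!is.null(ids[[1]])) {
    for (k in seq_along(cols)) {
      if (is.null(ids[[k]]) || !identical(sort(ids[[k]]), sort(ids[[1]])))
        stop_input("component PRSs cover different individual sets")
      cols[[k]] <- cols[[k]][ids[[1]]]
    }
  } else if (length(unique(lengths(cols))) != 1L) {
    stop_input("component PRSs have different lengths and no ids to align on")
  }
  labs <- names(components) %||% paste0("PRS", seq_along(cols))
  out <- do.call(cbind, cols)
  colnames(out) <- labs
  out
}

#' Unweighted sum of standardized component PRSs
#'
#' @param components List of `std_prs` objects (or named numeric vectors),
#'   a matrix, or a data.frame; all components must cover the same
#'   individuals.
#' @return Named numeric vector, the elementwise sum.
#' @export
sum_prs <- function(components) {
  M <- components_matrix(components)
  rowSums(M)
}

#' Weighted sum of component PRSs
#'
#' @param components As in [sum_prs()].
#' @param weights A `combination_weights` object or numeric vector aligned
#'   to the components (matched by label when both are named).
#' @return Named numeric vector sum_i w_i PRS_i.
#' @export
weighted_sum_prs <- function(components, weights) {
  M <- components_matrix(components)
  w <- if (inherits(weights, "combination_weights")) {
    setNames(weights$w, weights$labels)
  } else weights
  if (length(w) != ncol(M))
    stop_input("got ", length(w), " weights for ", ncol(M), " components")
  if (!is.null(names(w)) && !is.null(colnames(M))) {
    if (!setequal(names(w), colnames(M)))
      stop_input("weight labels do not match component labels")
    w <- w[colnames(M)]
  }
  drop(M %*% w)
}

#' Train multi-PRS combination weights by joint regression
#'
#' Ordinary least squares of the training phenotype on covariates plus all
#' component PRSs simultaneously; the combination weights are the fitted
#' coefficients of the components. Scope `"per_group"` restricts training
#' rows to one background group (the primary analysis); `"all"` uses every
#' training individual.
#'
#' @param data Training data.frame containing the outcome, covariates and
#'   a `group` column when scope is per-group.
#' @param outcome Outcome column name.
#' @param components As in [sum_prs()]; rows aligned with `data` (matched
#'   by `data$id` when components carry ids).
#' @param covariates Character vector of covariate column names (may be
#'   empty).
#' @param scope `"per_group"` or `"all"`.
#' @param group_value Group label to restrict to (scope per_group).
#' @param cohort_id Training-cohort label stored with the weights.
#' @return Object of class `combination_weights`: list with `labels`, `w`,
#'   `scope`, `group_value`, `covariates`, `cohort_id`, `n_train`.
#' @export
train_combination_weights <- function(data, outcome, components,
                                      covariates = character(0),
                                      scope = c("per_group", "all"),
                                      group_value = NULL,
                                      cohort_id = "training") {
  scope <- match.arg(scope)
  M <- components_matrix(components)
  if (!is.null(rownames(M)) && !is.null(data$id)) {
    if (!all(data$id %in% rownames(M)))
      stop_input("components missing for some training individuals")
    M <- M[data$id, , drop = FALSE]
  }
  if (nrow(M) != nrow(data))
    stop_input("components and training data cover different numbers of rows")
  rows <- seq_len(nrow(data))
  if (scope == "per_group") {
    if (is.null(group_value)) stop_input("scope 'per_group' requires group_value")
    rows <- which(data$group == group_value)
    if (length(rows) == 0L) stop_input("no training rows in group ", group_value)
  }
  df <- data[rows, , drop = FALSE]
  Mx <- M[rows, , drop = FALSE]
  labs <- colnames(Mx)
  fdat <- cbind(df[, c(outcome, covariates), drop = FALSE],
                as.data.frame(Mx))
  fml <- as.formula(paste(outcome, "~",
                          paste(c(covariates, labs), collapse = " + ")))
  fit <- lm(fml, data = fdat)
  co <- coef(fit)
  if (anyNA(co)) {
    bad <- names(co)[is.na(co)]
    stop_numeric("collinear design; aliased column(s): ",
                 paste(bad, collapse = ", "))
  }
  structure(list(labels = labs, w = unname(co[labs]), scope = scope,
                 group_value = group_value, covariates = covariates,
                 cohort_id = cohort_id, n_train = length(rows)),
            class = "combination_weights")
}

#' @export
print.combination_weights <- function(x, ...) {
  cat("PRS combination weights (", x$scope,
      if (!is.null(x$group_value)) paste0(": ", x$group_value), ", n = ",
      x$n_train, "):\n", sep = "")
  print(setNames(round(x$w, 4), x$labels))
  invisible(x)
}

#' Serialize / deserialize combination weights as JSON
#'
#' @param weights A `combination_weights` object.
#' @param path JSON path.
#' @return `path` (write) or a `combination_weights` object (read).
#' @export
write_combination_weights <- function(weights, path) {
  jsonlite::write_json(unclass(weights), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_combination_weights
#' @export
read_combination_weights <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$covariates <- as.character(x$covariates %||% character(0))
  structure(x, class = "combination_weights")
}

#' Scale or quantile-match a PRS distribution across datasets
#'
#' Harmonizes PRS distributions between the dataset the scores were
#' computed in (source) and a target dataset: `"none"` is the identity,
#' `"scale"` multiplies by sd(target)/sd(source) (means untouched beyond
#' reference standardization), and `"scale_match"` maps each value through
#' the source empirical CDF onto the target empirical quantile function
#' (monotone, rank-preserving; linear interpolation between order
#' statistics).
#'
#' @param prs_values Numeric vector of scores to transform (drawn from the
#'   source distribution).
#' @param source Numeric sample from the source distribution (>= 2
#'   values).
#' @param target Numeric sample from the target distribution (>= 2
#'   values).
#' @param mode `"none"`, `"scale"` or `"scale_match"`.
#' @return Transformed numeric vector, same length and names.
#' @export
scale_match_prs <- function(prs_values, source, target,
                            mode = c("none", "scale", "scale_match")) {
  mode <- match.arg(mode)
  if (mode == "none") return(prs_values)
  if (length(source) < 2L || length(target) < 2L)
    stop_input("source and target samples need >= 2 values")
  if (mode == "scale") {
    s_sd <- sd(source); t_sd <- sd(target)
    if (s_sd == 0) stop_numeric("source sample has zero SD")
    return(prs_values / s_sd * t_sd)
  }
  # scale_match: empirical-quantile mapping with mid-rank plotting positions
  u <- ecdf(source)(prs_values)
  u <- pmin(pmax(u, 1 / (2 * length(source))), 1 - 1 / (2 * length(source)))
  out <- as.numeric(quantile(target, probs = u, type = 7, names = FALSE))
  names(out) <- names(prs_values)
  out
}
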