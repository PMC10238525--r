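# Phenotype preparation: antihypertensive-medication adjustment, stratum
# labels, and kinship-based unrelated-subset selection.

#' Adjust blood pressure for antihypertensive medication use
#'
#' Adds 15 mmHg to SBP and 10 mmHg to DBP in individuals using
#' antihypertensive medication — the standard adjustment approximating
#' the untreated value. Adds `sbp_adj`, `dbp_adj` and a provenance flag
#' `adjusted`; applying the adjustment twice is an error.
#'
#' @param pheno data.frame with columns `sbp`, `dbp`, `med_use` (logical).
#' @param missing_policy `"lenient"` (missing med_use left unchanged,
#'   counted) or `"strict"` (error on missing med_use).
#' @param sbp_delta,dbp_delta Adjustment in mmHg (defaults 15 and 10).
#' @return `pheno` with `sbp_adj`, `dbp_adj`, `adjusted = TRUE`; attribute
#'   `n_missing_med` counts unadjudicated records under the lenient
#'   policy.
#' @export
adjust_for_medication <- function(pheno, missing_policy = c("lenient", "strict"),
                                  sbp_delta = 15, dbp_delta = 10) {
  missing_policy <- match.arg(missing_policy)
  if (isTRUE(attr(pheno, "adjusted")) || isTRUE(pheno$adjusted[1]))
    stop_input("phenotypes are already medication-adjusted; refusing to re-apply")
  miss <- is.na(pheno$med_use)
  if (any(miss) && missing_policy == "strict")
    stop_input(sum(miss), " record(s) have missing med_use under strict policy")
  med <- !miss & pheno$med_use
  pheno$sbp_adj <- pheno$sbp + ifelse(med, sbp_delta, 0)
  pheno$dbp_adj <- pheno$dbp + ifelse(med, dbp_delta, 0)
  pheno$adjusted <- TRUE
  if (any(miss))
    message("adjust_for_medication: ", sum(miss),
            " record(s) with missing med_use left unchanged")
  attr(pheno, "n_missing_med") <- sum(miss)
  attr(pheno, "adjusted") <- TRUE
  pheno
}

#' Assign evaluation strata labels
#'
#' Age bands <=40, (40, 60], >60; obesity defined as BMI >= 30; sex and
#' medication-use strata copied through as labels. Records with a missing
#' field get NA for that stratification (excluded from it downstream).
#'
#' @param pheno data.frame with `age`, `sex`, `bmi`, `med_use`.
#' @return `pheno` with added columns `age_band` (factor:
#'   `"<=40"`, `"40-60"`, `">60"`), `obese` (logical), `sex_label`,
#'   `med_stratum`.
#' @export
assign_strata <- function(pheno) {
  pheno$age_band <- cut(pheno$age, breaks = c(-Inf, 40, 60, Inf),
                        labels = c("<=40", "40-60", ">60"), right = TRUE)
  pheno$obese <- pheno$bmi >= 30
  pheno$sex_label <- ifelse(is.na(pheno$sex), NA_character_,
                            ifelse(pheno$sex == 1 | pheno$sex == "male",
                                   "male", "female"))
  pheno$med_stratum <- ifelse(is.na(pheno$med_use), NA_character_,
                              ifelse(pheno$med_use, "med_user", "non_user"))
  pheno
}

#' Select an unrelated subset from a kinship edge list
#'
#' Greedy elimination: repeatedly drop the individual participating in the
#' most pairs with kinship above `threshold` (ties broken by dropping the
#' lexicographically larger id) until no above-threshold pair remains.
#' The default threshold 2^-4.5 (~ 4.4%) corresponds to third-degree
#' relatedness.
#'
#' @param kinship_edges data.frame with columns id1, id2, kinship (sparse:
#'   only positive-kinship pairs need be listed), or a square kinship
#'   matrix.
#' @param ids Optional character vector of all cohort ids (individuals
#'   without edges are always retained); defaults to ids appearing in the
#'   edge list.
#' @param threshold Kinship threshold (default `2^-4.5`).
#' @return Character vector of retained ids (sorted).
#' @export
select_unrelated <- function(kinship_edges, ids = NULL, threshold = 2^-4.5) {
  if (is.matrix(kinship_edges)) {
    ids <- ids %||% rownames(kinship_edges)
    kinship_edges <- kinship_edges(kinship_edges, min_kinship = 0)
  }
  e <- kinship_edges[kinship_edges$kinship > threshold, , drop = FALSE]
  all_ids <- unique(c(ids, kinship_edges$id1, kinship_edges$id2))
  dropped <- character(0)
  while (nrow(e) > 0L) {
    deg <- table(c(e$id1, e$id2))
    worst <- names(deg)[deg == max(deg)]
    victim <- max(worst)                      # lexicographically larger id
    dropped <- c(dropped, victim)
    e <- e[e$id1 != victim & e$id2 != victim, , drop = FALSE]
  }
  sort(setdiff(all_ids, dropped))
}
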