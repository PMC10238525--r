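# End-to-end driver: simulate -> harmonize -> clump -> score ->
# standardize -> combine -> prep -> evaluate -> diagnostics, with a run
# report carrying seeds, row counts and output hashes.

#' Pipeline configuration
#'
#' Builds and validates the configuration consumed by [run_pipeline()].
#' Defaults mirror the standard analysis parameters: clumping r^2 = 0.1
#' over 1000 kb, p-value thresholds 5e-8 / 1e-5 / 1e-2, kinship threshold
#' 2^-4.5, ancestry-group cutoff 0.8, +15/+10 mmHg medication adjustment,
#' and percentile bootstrap.
#'
#' @param cohort A [cohort_config()] describing the simulated cohort.
#' @param trait `"sbp"` or `"dbp"`.
#' @param r2_max,window_kb Clumping parameters.
#' @param p_thresholds P-value thresholds for clump-and-threshold PRSs.
#' @param combination_scope `"all"` or `"per_group"` for weight training.
#' @param strata Stratum columns for the evaluation stage.
#' @param n_boot Bootstrap replicates for evaluation CIs (0 = none).
#' @param kinship_threshold Unrelated-selection kinship cutoff.
#' @param ancestry_cutoff Majority-ancestry grouping cutoff.
#' @param train_fraction Fraction of the cohort held out to train
#'   combination weights.
#' @param seed Integer seed governing every stochastic stage.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            trait = "sbp",
                            r2_max = 0.1, window_kb = 1000,
                            p_thresholds = c(5e-8, 1e-5, 1e-2),
                            combination_scope = "all",
                            strata = c("group", "age_band", "sex_label",
                                       "obese", "med_stratum"),
                            n_boot = 0L,
                            kinship_threshold = 2^-4.5,
                            ancestry_cutoff = 0.8,
                            train_fraction = 0.4,
                            seed = NULL) {
  if (is.null(seed) || is.na(suppressWarnings(as.integer(seed))))
    stop_config("pipeline config requires an explicit integer seed")
  if (!trait %in% c("sbp", "dbp")) stop_config("trait must be sbp or dbp")
  if (any(p_thresholds <= 0 | p_thresholds > 1))
    stop_config("p_thresholds must lie in (0, 1]")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop_config("train_fraction must be in (0, 1)")
  for (pp in c(r2_max, kinship_threshold, ancestry_cutoff))
    if (pp <= 0 || pp >= 1) stop_config("fractions must be in (0, 1)")
  structure(list(cohort = cohort, trait = trait, r2_max = r2_max,
                 window_kb = window_kb, p_thresholds = p_thresholds,
                 combination_scope = combination_scope, strata = strata,
                 n_boot = as.integer(n_boot),
                 kinship_threshold = kinship_threshold,
                 ancestry_cutoff = ancestry_cutoff,
                 train_fraction = train_fraction,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Scalar keys override [pipeline_config()] defaults; cohort-level keys
#' go under a `cohort:` block and override [cohort_config()] defaults.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort_args <- y$cohort %||% list()
  if (!is.null(cohort_args$ancestries)) {
    cohort_args$ancestries <- lapply(cohort_args$ancestries, function(a)
      ancestry_spec(a$name, a$fst, a$n_train_gwas %||% 10000L))
  }
  for (nm in c("n_per_group", "group_residual_sd_sbp", "group_residual_sd_dbp",
               "med_use_prob"))
    if (!is.null(cohort_args[[nm]])) cohort_args[[nm]] <- unlist(cohort_args[[nm]])
  cohort_args$seed <- cohort_args$seed %||% y$seed
  y$cohort <- do.call(cohort_config, cohort_args)
  do.call(pipeline_config, y)
}

#' Demo pipeline configuration
#'
#' Two ancestries, 600 variants, ~1200 individuals: small enough for a
#' test run, large enough to exercise every stage.
#'
#' @param seed Integer seed.
#' @return A `pipeline_config`.
#' @export
demo_config <- function(seed = 42L) {
  cc <- cohort_config(
    ancestries = list(ancestry_spec("EUR", 0.05, 50000L),
                      ancestry_spec("AFR", 0.15, 20000L)),
    n_per_group = c(EUR = 700L, AFR = 500L),
    m_variants = 600L, m_causal = 60L,
    group_residual_sd_sbp = c(EUR = 17, AFR = 19),
    group_residual_sd_dbp = c(EUR = 10, AFR = 11.18),
    med_use_prob = c(EUR = 0.25, AFR = 0.25),
    relatedness_pairs = 10L,
    heritability_prs = 0.15,
    seed = seed)
  pipeline_config(cohort = cc, p_thresholds = c(1e-4, 1e-2),
                  strata = c("group", "sex_label"), n_boot = 0L, seed = seed)
}

#' Run the end-to-end PRS pipeline
#'
#' Simulates a cohort, simulates per-population GWAS summary statistics,
#' harmonizes them to the panel, builds clump-and-threshold PRSs at each
#' p-value threshold, scores and standardizes them against the evaluation
#' cohort, trains combination weights on a held-out training split, forms
#' unweighted and weighted PRS sums, prepares phenotypes
#' (medication-adjusts, labels strata, selects unrelated individuals) and
#' evaluates every PRS stratified by the configured strata, plus ancestry
#' diagnostics. All outputs are written under `out_dir` with MD5 hashes
#' in the run report.
#'
#' @param config A `pipeline_config` (or YAML path).
#' @param out_dir Output directory.
#' @return List with `evaluation` (the evaluation table),
#'   `combination_weights`, `report` (run metadata), invisibly the file
#'   paths in `report$outputs`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  report <- list(seed = config$seed, stages = list())
  log_stage <- function(name, ...) {
    report$stages[[name]] <<- c(list(...),
                                wall_time = round(as.numeric(Sys.time() - t0, units = "secs"), 2))
    message(sprintf("[%s] %s", name,
                    paste(names(list(...)), unlist(list(...)), sep = "=",
                          collapse = " ")))
  }

  ## simulate
  cohort <- simulate_cohort(config$cohort)
  sim_files <- write_cohort(cohort, file.path(out_dir, "sim"), write_vcf = FALSE)
  labs <- colnames(cohort$pop_freqs)
  log_stage("simulate", n = nrow(cohort$genotypes$dosage),
            m = ncol(cohort$genotypes$dosage))

  ## per-population GWAS summary statistics (analytic mode)
  group <- cohort$phenotypes$group
  sumstats <- list()
  for (k in seq_along(labs)) {
    anc <- config$cohort$ancestries[[k]]
    sumstats[[anc$name]] <- simulate_gwas_sumstats(
      cohort$genotypes, cohort$phenotypes,
      subset = which(group == anc$name), trait = config$trait,
      mode = "analytic", n_gwas = anc$n_train_gwas,
      seed = derive_seed(config$seed, 20L + k))
  }
  log_stage("gwas", n_gwas = length(sumstats))

  ## harmonize + QC against panel
  pstats <- panel_stats(cohort$genotypes)
  params_list <- lapply(config$p_thresholds, function(p)
    clump_params(config$r2_max, config$window_kb, p))
  harmonized <- lapply(sumstats, function(ss) {
    ssq <- qc_filter(ss[!ss$missing, ], pstats$freqs, pstats$missingness)
    harmonize_alleles(ssq, cohort$genotypes$variants)
  })
  log_stage("harmonize",
            retained = paste(vapply(harmonized, nrow, integer(1)), collapse = ","))

  ## split: training (combination weights) vs evaluation cohort
  set.seed(derive_seed(config$seed, 31L))
  n <- nrow(cohort$phenotypes)
  train_idx <- sort(sample.int(n, round(config$train_fraction * n)))
  eval_idx <- setdiff(seq_len(n), train_idx)
  eval_ids <- cohort$phenotypes$id[eval_idx]

  ## clump + threshold + score + standardize (reference = evaluation cohort)
  components <- list()
  weight_files <- character(0)
  for (gname in names(harmonized)) {
    for (params in params_list) {
      idx_set <- suppressWarnings(
        ld_clump(harmonized[[gname]], cohort$genotypes, params))
      if (length(idx_set) == 0L) next
      wt <- threshold_weights(harmonized[[gname]], idx_set, params$p_threshold,
                              source = sprintf("%s_p%g", gname, params$p_threshold))
      label <- sprintf("%s_p%g", gname, params$p_threshold)
      wf <- file.path(out_dir, paste0("weights_", label, ".tsv"))
      write_weight_table(wt, wf)
      weight_files <- c(weight_files, wf)
      raw <- score_prs(cohort$genotypes, wt)
      components[[label]] <- standardize_prs(raw, reference = raw[eval_ids],
                                             ref_id = "evaluation_cohort")
    }
  }
  if (length(components) == 0L) stop_numeric("no PRS produced at any threshold")
  log_stage("construct", n_prs = length(components))

  ## combine: train weights on the training split
  pheno <- cohort$phenotypes
  pheno_train <- pheno[train_idx, , drop = FALSE]
  covars <- c("age", "sex", "bmi")
  cw <- train_combination_weights(pheno_train, config$trait, components,
                                  covariates = covars,
                                  scope = config$combination_scope,
                                  group_value = if (config$combination_scope ==
                                                    "per_group") labs[1L],
                                  cohort_id = "training_split")
  write_combination_weights(cw, file.path(out_dir, "combination_weights.json"))
  prs_tab <- as.data.frame(components_matrix(components))
  prs_tab$PRS_sum <- sum_prs(components)
  prs_tab$PRS_weighted <- weighted_sum_prs(components, cw)
  log_stage("combine", n_components = length(cw$labels))

  ## prep: medication adjustment, strata, unrelated subset
  pheno <- adjust_for_medication(pheno)
  pheno <- assign_strata(pheno)
  unrelated <- select_unrelated(cohort$kinship_edges, ids = eval_ids,
                                threshold = config$kinship_threshold)
  unrelated <- intersect(unrelated, eval_ids)
  write.table(pheno, file.path(out_dir, "phenotypes_prepped.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(unrelated, file.path(out_dir, "unrelated_ids.txt"))
  log_stage("prep", n_unrelated = length(unrelated))

  ## evaluate each PRS on the evaluation cohort
  outcome <- paste0(config$trait, "_adj")
  eval_df <- cbind(pheno, prs_tab[match(pheno$id, rownames(cohort$genotypes$dosage)), ,
                                  drop = FALSE])
  eval_df <- eval_df[eval_df$id %in% eval_ids, , drop = FALSE]
  eval_rows <- list()
  for (lab in colnames(prs_tab)) {
    eval_rows[[lab]] <- stratified_evaluation(
      eval_df, outcome, lab, covariates = c("age", "sex", "bmi"),
      group_intercepts = if (length(labs) > 1L) "group" else NULL,
      strata = config$strata, unrelated_ids = unrelated,
      n_boot = config$n_boot, seed = derive_seed(config$seed, 41L),
      prs_label = lab)
  }
  evaluation <- do.call(rbind, eval_rows)
  rownames(evaluation) <- NULL
  eval_file <- file.path(out_dir, "evaluation.tsv")
  write.table(evaluation, eval_file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  log_stage("evaluate", n_rows = nrow(evaluation))

  ## ancestry diagnostics
  best <- names(components)[1L]
  freqs <- estimate_ancestry_freqs(cohort$genotypes$dosage,
                                   cohort$genotypes$proportions)
  anc_group <- assign_ancestry_group(cohort$genotypes$proportions,
                                     cutoff = config$ancestry_cutoff)
  profile <- effect_frequency_profile(harmonized[[1L]], freqs)
  write.table(freqs, file.path(out_dir, "ancestry_freqs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(profile))
    write.table(profile, file.path(out_dir, "effect_profile.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  log_stage("diagnostics", n_assigned = sum(!is.na(anc_group)))

  ## run report with output hashes
  outputs <- c(sim_files, weight_files,
               combination_weights = file.path(out_dir, "combination_weights.json"),
               phenotypes_prepped = file.path(out_dir, "phenotypes_prepped.tsv"),
               unrelated = file.path(out_dir, "unrelated_ids.txt"),
               evaluation = eval_file,
               ancestry_freqs = file.path(out_dir, "ancestry_freqs.tsv"))
  outputs <- outputs[file.exists(outputs)]
  report$outputs <- lapply(seq_along(outputs), function(i)
    list(path = unname(outputs[i]), md5 = unname(tools::md5sum(outputs[i]))))
  report$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(evaluation = evaluation, combination_weights = cw,
                 components = components, report = report,
                 unrelated_ids = unrelated, cohort = cohort))
}
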