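# Multi-ancestry cohort simulator: Balding-Nichols allele-frequency
# divergence, block LD via latent-uniform haplotype copying, admixed
# dosages, polygenic phenotypes with group-specific residual variances,
# injected relatedness, and per-population GWAS summary statistics.

#' Describe a simulated ancestral population
#'
#' @param name Population label (e.g. `"EUR"`).
#' @param fst Balding-Nichols divergence of this population from the shared
#'   ancestral pool, in (0, 1).
#' @param n_train_gwas Sample size of the simulated GWAS for this population
#'   (used by [simulate_gwas_sumstats()] in analytic mode).
#' @return A list of class `ancestry_spec`.
#' @export
ancestry_spec <- function(name, fst, n_train_gwas = 10000L) {
  if (!is.numeric(fst) || length(fst) != 1L || fst <= 0 || fst >= 1)
    stop_config("fst must be a single number in (0, 1), got ", format(fst))
  if (n_train_gwas < 1) stop_config("n_train_gwas must be >= 1")
  structure(list(name = as.character(name), fst = fst,
                 n_train_gwas = as.integer(n_train_gwas)),
            class = "ancestry_spec")
}

#' Cohort simulation configuration
#'
#' Defaults describe the study conditions the simulator emulates: three
#' ancestral populations (European-, African- and East-Asian-like), systolic
#' blood pressure (SBP) residual SDs of 17/19/18 mmHg so the AFR-like group
#' has (19/17)^2 ~ 25% higher residual variance than the EUR-like group,
#' diastolic (DBP) SDs 10/11.18/10.5 mmHg, 5% of residual phenotypic
#' variance attributable to causal variants, and a 25% antihypertensive
#' medication-use probability.
#'
#' @param ancestries List of [ancestry_spec()] objects.
#' @param n_per_group Integer vector (named by ancestry) of individuals per
#'   group.
#' @param m_variants Number of variants.
#' @param m_causal Number of causal variants (must be <= `m_variants`).
#' @param ld_block_size Variants per LD block.
#' @param ld_rho Within-block latent copying probability controlling LD.
#' @param heritability_prs Fraction of residual (non-covariate) phenotypic
#'   variance explained by causal variants, in \[0, 1).
#' @param covariate_effects Named list with SBP-scale effects for `age`
#'   (mmHg/year), `age2`, `sex` (male indicator), `bmi` (mmHg per kg/m^2)
#'   and `smoking_current`.
#' @param group_residual_sd_sbp,group_residual_sd_dbp Named numeric vectors
#'   of per-group residual SDs (mmHg).
#' @param med_use_prob Named numeric vector of per-group medication-use
#'   probabilities.
#' @param relatedness_pairs Number of first-degree-like pairs to inject.
#' @param freq_range Ancestral allele-frequency range.
#' @param pos_spacing Base-pair spacing between adjacent variants.
#' @param seed Integer RNG seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(ancestries = list(ancestry_spec("EUR", 0.05, 500000L),
                                            ancestry_spec("AFR", 0.15, 30000L),
                                            ancestry_spec("EAS", 0.12, 130000L)),
                          n_per_group = c(EUR = 1500L, AFR = 1000L, EAS = 500L),
                          m_variants = 1000L,
                          m_causal = 100L,
                          ld_block_size = 10L,
                          ld_rho = 0.7,
                          heritability_prs = 0.05,
                          covariate_effects = list(age = 0.45, age2 = 0.003,
                                                   sex = 3, bmi = 0.7,
                                                   smoking_current = 2),
                          group_residual_sd_sbp = c(EUR = 17, AFR = 19, EAS = 18),
                          group_residual_sd_dbp = c(EUR = 10, AFR = 11.18, EAS = 10.5),
                          med_use_prob = c(EUR = 0.25, AFR = 0.25, EAS = 0.25),
                          relatedness_pairs = 0L,
                          freq_range = c(0.05, 0.95),
                          pos_spacing = 2000L,
                          seed = 1L) {
  if (heritability_prs < 0 || heritability_prs >= 1)
    stop_config("heritability_prs must be in [0, 1)")
  if (m_causal > m_variants)
    stop_config("m_causal (", m_causal, ") exceeds m_variants (", m_variants, ")")
  if (any(group_residual_sd_sbp <= 0) || any(group_residual_sd_dbp <= 0))
    stop_config("all residual SDs must be > 0")
  labs <- vapply(ancestries, `[[`, character(1), "name")
  for (nm in c("n_per_group", "group_residual_sd_sbp", "group_residual_sd_dbp",
               "med_use_prob")) {
    v <- get(nm)
    if (!all(labs %in% names(v)))
      stop_config(nm, " must be named by ancestry labels: ",
                  paste(labs, collapse = ", "))
  }
  structure(list(ancestries = ancestries, n_per_group = n_per_group,
                 m_variants = as.integer(m_variants),
                 m_causal = as.integer(m_causal),
                 ld_block_size = as.integer(ld_block_size), ld_rho = ld_rho,
                 heritability_prs = heritability_prs,
                 covariate_effects = covariate_effects,
                 group_residual_sd_sbp = group_residual_sd_sbp,
                 group_residual_sd_dbp = group_residual_sd_dbp,
                 med_use_prob = med_use_prob,
                 relatedness_pairs = as.integer(relatedness_pairs),
                 freq_range = freq_range,
                 pos_spacing = as.integer(pos_spacing),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Simulate ancestral allele frequencies
#'
#' Draws the shared ancestral-pool allele frequencies used as the mean of
#' the Balding-Nichols divergence model.
#'
#' @param m_variants Number of variants.
#' @param freq_range Length-2 numeric, frequencies drawn uniformly on this
#'   interval (must lie inside (0, 1)).
#' @param seed Integer seed.
#' @return Numeric vector of length `m_variants`.
#' @export
simulate_ancestral_frequencies <- function(m_variants, freq_range = c(0.05, 0.95),
                                           seed = 1L) {
  if (length(freq_range) != 2L || freq_range[1] > freq_range[2])
    stop_config("freq_range must be an interval lo <= hi, got ",
                paste(freq_range, collapse = ", "))
  if (freq_range[1] <= 0 || freq_range[2] >= 1)
    stop_config("freq_range must be inside (0, 1)")
  set.seed(seed)
  runif(m_variants, freq_range[1], freq_range[2])
}

#' Simulate population allele frequencies under Balding-Nichols divergence
#'
#' For each variant with ancestral frequency p and divergence F (FST), the
#' population frequency is drawn from Beta(p(1-F)/F, (1-p)(1-F)/F), which
#' has mean p and variance F p(1-p).
#'
#' @param ancestral_freqs Ancestral frequency vector.
#' @param fst Divergence in (0, 1).
#' @param seed Integer seed.
#' @return Numeric vector, same length, each value in (0, 1).
#' @export
simulate_population_frequencies <- function(ancestral_freqs, fst, seed = 1L) {
  if (!is.numeric(fst) || length(fst) != 1L || fst <= 0 || fst >= 1)
    stop_config("fst must be in (0, 1), got ", format(fst))
  set.seed(seed)
  p <- rbeta(length(ancestral_freqs),
             ancestral_freqs * (1 - fst) / fst,
             (1 - ancestral_freqs) * (1 - fst) / fst)
  pmin(pmax(p, 1e-6), 1 - 1e-6)
}

# One haplotype matrix (n x m, 0/1) with block LD: within each block a
# latent uniform is carried over to the next variant with probability rho,
# so adjacent indicators share their uniform and are positively correlated
# while marginal frequencies are untouched.
simulate_haplotypes <- function(p_ind, blocks, rho) {
  n <- nrow(p_ind); m <- ncol(p_ind)
  u <- matrix(NA_real_, n, m)
  for (j in seq_len(m)) {
    if (j == 1L || blocks[j] != blocks[j - 1L]) {
      u[, j] <- runif(n)
    } else {
      keep <- runif(n) < rho
      u[, j] <- ifelse(keep, u[, j - 1L], runif(n))
    }
  }
  (u < p_ind) * 1L
}

#' Simulate admixed genotype dosages with block LD
#'
#' Each individual's per-variant expected allele frequency is the
#' admixture-weighted mix of population frequencies,
#' p_ij = sum_k q_ik p_jk. Two haplotypes are drawn per individual with
#' block-structured LD; dosages are their sum. Optionally the first
#' `relatedness_pairs` consecutive pairs of individuals share one full
#' haplotype (first-degree-like relatedness, kinship ~ 0.25).
#'
#' @param pop_freqs m x K matrix of per-population allele frequencies
#'   (columns named by population).
#' @param ancestry_proportions n x K matrix of admixture proportions (rows
#'   sum to 1).
#' @param ld_block_size Variants per LD block (1 = independent variants).
#' @param ld_rho Within-block latent copying probability.
#' @param relatedness_pairs Number of sib-like pairs to inject (pairs
#'   (1,2), (3,4), ...; the second member also inherits the first's
#'   ancestry proportions).
#' @param chrom Chromosome label(s); variants are split evenly across them.
#' @param pos_spacing Base-pair spacing between adjacent variants.
#' @param seed Integer seed.
#' @return An object of class `genotype_matrix`: list with `dosage`
#'   (n x m integer matrix, columns named by variant id), `variants`
#'   (data.frame: id, chrom, pos, other_allele, effect_allele) and
#'   `proportions` (n x K matrix).
#' @export
simulate_genotypes <- function(pop_freqs, ancestry_proportions,
                               ld_block_size = 10L, ld_rho = 0.7,
                               relatedness_pairs = 0L,
                               chrom = "1", pos_spacing = 2000L, seed = 1L) {
  pop_freqs <- as.matrix(pop_freqs)
  Q <- as.matrix(ancestry_proportions)
  if (ncol(Q) != ncol(pop_freqs))
    stop_input("ancestry_proportions has ", ncol(Q), " columns but pop_freqs has ",
               ncol(pop_freqs), " populations")
  if (any(Q < 0) || any(abs(rowSums(Q) - 1) > 1e-8))
    stop_input("ancestry proportions must be nonnegative and sum to 1 per row")
  n <- nrow(Q); m <- nrow(pop_freqs)
  set.seed(seed)

  p_ind <- Q %*% t(pop_freqs)                       # n x m expected frequency
  blocks <- rep(seq_len(ceiling(m / ld_block_size)), each = ld_block_size)[seq_len(m)]
  h1 <- simulate_haplotypes(p_ind, blocks, ld_rho)
  h2 <- simulate_haplotypes(p_ind, blocks, ld_rho)

  if (relatedness_pairs > 0L) {
    if (2L * relatedness_pairs > n)
      stop_input("relatedness_pairs requires at least ", 2L * relatedness_pairs,
                 " individuals")
    for (k in seq_len(relatedness_pairs)) {
      a <- 2L * k - 1L; b <- 2L * k
      Q[b, ] <- Q[a, ]
      # b redraws haplotype 2 under a's expected frequencies, shares hap 1
      h1[b, ] <- h1[a, ]
      p_b <- matrix(Q[b, ] %*% t(pop_freqs), nrow = 1L)
      h2[b, ] <- simulate_haplotypes(p_b[rep(1L, 1L), , drop = FALSE], blocks, ld_rho)
    }
  }
  dosage <- h1 + h2

  chrom <- rep(chrom, each = ceiling(m / length(chrom)))[seq_len(m)]
  pos <- integer(m)
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    pos[idx] <- seq_along(idx) * pos_spacing
  }
  # unambiguous allele pairs so synthetic panels survive harmonization intact
  pair <- matrix(c("A", "C", "A", "G", "T", "C", "T", "G",
                   "C", "A", "G", "A", "C", "T", "G", "T"),
                 ncol = 2L, byrow = TRUE)
  pick <- sample.int(nrow(pair), m, replace = TRUE)
  variants <- data.frame(id = variant_id(chrom, pos, pair[pick, 1L], pair[pick, 2L]),
                         chrom = chrom, pos = pos,
                         other_allele = pair[pick, 1L],
                         effect_allele = pair[pick, 2L],
                         stringsAsFactors = FALSE)
  colnames(dosage) <- variants$id
  rownames(dosage) <- sprintf("ind_%04d", seq_len(n))
  rownames(Q) <- rownames(dosage)
  structure(list(dosage = dosage, variants = variants, proportions = Q,
                 relatedness_pairs = as.integer(relatedness_pairs)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "individuals x", ncol(x$dosage),
      "variants,", ncol(x$proportions), "ancestries\n")
  invisible(x)
}

#' Draw causal per-allele effects for the simulated traits
#'
#' Effects are standard-normal draws on `m_causal` variants chosen at
#' random (zero elsewhere); the overall scale is set later by
#' [simulate_phenotypes()] to hit the configured heritability. DBP effects
#' are correlated with SBP effects (r ~ 0.7), mimicking the shared genetic
#' architecture of the two pressure traits.
#'
#' @param config A [cohort_config()].
#' @return List with numeric vectors `sbp` and `dbp` of length `m_variants`
#'   and integer vector `causal_idx`.
#' @export
simulate_causal_effects <- function(config) {
  set.seed(derive_seed(config$seed, 11L))
  m <- config$m_variants
  idx <- sort(sample.int(m, config$m_causal))
  b_sbp <- b_dbp <- numeric(m)
  z1 <- rnorm(config$m_causal); z2 <- rnorm(config$m_causal)
  b_sbp[idx] <- z1
  b_dbp[idx] <- 0.7 * z1 + sqrt(1 - 0.7^2) * z2
  list(sbp = b_sbp, dbp = b_dbp, causal_idx = idx)
}

#' Simulate phenotypes and covariates for a synthetic cohort
#'
#' Builds SBP- and DBP-like traits as baseline + covariate effects +
#' scaled genetic value + group-specific Gaussian noise. The genetic value
#' g = X beta is rescaled so that var(g) / (var(g) + var(e)) equals
#' `heritability_prs`, where var(e) is the admixture-weighted mean of the
#' group residual variances; so the configured heritability is the fraction
#' of residual (covariate-free) phenotypic variance explained by the causal
#' variants — the quantity the PVE statistic estimates. Observed BP of
#' medication users is lowered by 15/10 mmHg (SBP/DBP), the treatment
#' effect the standard medication adjustment reverses.
#'
#' @param genotypes A `genotype_matrix`.
#' @param causal_effects List with `sbp` and `dbp` per-variant effect
#'   vectors (see [simulate_causal_effects()]).
#' @param config A [cohort_config()].
#' @param group Optional character vector of group labels per individual;
#'   defaults to the ancestry with the largest proportion.
#' @param seed Integer seed (defaults to the config seed).
#' @return data.frame with columns id, group, age, sex, bmi, smoking,
#'   med_use, sbp, dbp; attributes `genetic_sbp`, `genetic_dbp` (true
#'   genetic values) and `truth` (scaling constants) support recovery
#'   tests.
#' @export
simulate_phenotypes <- function(genotypes, causal_effects, config,
                                group = NULL, seed = NULL) {
  X <- genotypes$dosage
  n <- nrow(X)
  h2 <- config$heritability_prs
  if (length(causal_effects$sbp) != ncol(X))
    stop_input("causal effect vector length ", length(causal_effects$sbp),
               " does not match ", ncol(X), " variants")
  if (h2 > 0 && all(causal_effects$sbp == 0) && all(causal_effects$dbp == 0))
    stop_config("heritability_prs > 0 requested but all causal effects are zero")
  set.seed(seed %||% derive_seed(config$seed, 13L))

  if (is.null(group)) {
    labs <- colnames(genotypes$proportions) %||%
      vapply(config$ancestries, `[[`, character(1), "name")
    group <- labs[max.col(genotypes$proportions)]
  }
  sd_sbp <- config$group_residual_sd_sbp[group]
  sd_dbp <- config$group_residual_sd_dbp[group]

  age <- runif(n, 30, 80)
  sex <- rbinom(n, 1L, 0.5)                          # 1 = male
  bmi <- pmax(rnorm(n, 28, 5), 15)
  smoking <- sample(c("never", "former", "current"), n, replace = TRUE,
                    prob = c(0.5, 0.3, 0.2))
  med_use <- rbinom(n, 1L, config$med_use_prob[group]) == 1L

  ce <- config$covariate_effects
  cov_part <- ce$age * (age - 55) + ce$age2 * (age - 55)^2 +
    ce$sex * sex + ce$bmi * (bmi - 28) +
    ce$smoking_current * (smoking == "current")

  scale_g <- function(beta, resid_var) {
    if (h2 == 0 || all(beta == 0)) return(list(g = numeric(n), s = 0))
    g <- drop(X %*% beta)
    # heritability is defined on the within-group genetic variance: the
    # between-group component (allele-frequency differences) is absorbed
    # by group intercepts in evaluation models, so scaling on it would
    # understate the score's explanatory share
    vg <- var(g - ave(g, group))
    if (vg == 0) stop_config("causal genetic value is constant; cannot reach heritability_prs")
    s <- sqrt(h2 / (1 - h2) * resid_var / vg)
    list(g = g * s, s = s)
  }
  gs <- scale_g(causal_effects$sbp, mean(sd_sbp^2))
  gd <- scale_g(causal_effects$dbp, mean(sd_dbp^2))

  sbp <- 120 + cov_part + gs$g + rnorm(n, 0, sd_sbp)
  dbp <- 75 + 0.5 * cov_part + gd$g + rnorm(n, 0, sd_dbp)
  # observed BP is lowered by treatment in medication users
  sbp[med_use] <- sbp[med_use] - 15
  dbp[med_use] <- dbp[med_use] - 10

  out <- data.frame(id = rownames(X), group = group, age = age, sex = sex,
                    bmi = bmi, smoking = smoking, med_use = med_use,
                    sbp = sbp, dbp = dbp, stringsAsFactors = FALSE)
  attr(out, "genetic_sbp") <- gs$g
  attr(out, "genetic_dbp") <- gd$g
  attr(out, "truth") <- list(heritability_prs = h2, scale_sbp = gs$s,
                             scale_dbp = gd$s,
                             group_residual_sd_sbp = config$group_residual_sd_sbp,
                             group_residual_sd_dbp = config$group_residual_sd_dbp)
  out
}

# Covariate design used by the simulated GWAS (age, age^2, sex, bmi, smoking).
gwas_covariate_matrix <- function(phenotypes) {
  cbind(1, phenotypes$age, phenotypes$age^2, phenotypes$sex, phenotypes$bmi,
        phenotypes$smoking == "former", phenotypes$smoking == "current")
}

#' Simulate GWAS summary statistics for a population subset
#'
#' Regression mode runs the actual covariate-adjusted single-SNP
#' regressions on the subset (via Frisch-Waugh residualization, exact and
#' vectorized). Analytic mode emulates a large external GWAS of size
#' `n_gwas`: the true covariate-adjusted marginal effect of each variant is
#' measured in the subset, and the reported estimate is drawn as
#' beta_hat ~ Normal(beta_marginal, se) with
#' se = sd_resid / sqrt(2 n_gwas p (1 - p)).
#'
#' @param genotypes A `genotype_matrix`.
#' @param phenotypes Output of [simulate_phenotypes()].
#' @param subset Logical or integer index of individuals forming the GWAS
#'   population (default: all).
#' @param trait `"sbp"` or `"dbp"`.
#' @param mode `"regression"` or `"analytic"`.
#' @param n_gwas Emulated sample size (analytic mode; defaults to subset
#'   size).
#' @param seed Integer seed (analytic mode noise).
#' @return data.frame with columns chrom, pos, effect_allele, other_allele,
#'   beta, se, pval, eaf, n (one row per variant; monomorphic variants get
#'   NA effect and `missing = TRUE`).
#' @export
simulate_gwas_sumstats <- function(genotypes, phenotypes, subset = NULL,
                                   trait = c("sbp", "dbp"),
                                   mode = c("regression", "analytic"),
                                   n_gwas = NULL, seed = 1L) {
  trait <- match.arg(trait)
  mode <- match.arg(mode)
  if (is.null(subset)) subset <- seq_len(nrow(genotypes$dosage))
  X <- genotypes$dosage[subset, , drop = FALSE]
  ph <- phenotypes[subset, , drop = FALSE]
  if (nrow(X) == 0L) stop_input("population subset is empty")
  y <- ph[[trait]]
  n <- nrow(X)
  m <- ncol(X)
  eaf <- colMeans(X) / 2
  mono <- eaf <= 0 | eaf >= 1

  C <- gwas_covariate_matrix(ph)
  qc <- qr(C)
  ry <- qr.resid(qc, y)

  v <- genotypes$variants
  out <- data.frame(chrom = v$chrom, pos = v$pos,
                    effect_allele = v$effect_allele,
                    other_allele = v$other_allele,
                    beta = NA_real_, se = NA_real_, pval = NA_real_,
                    eaf = eaf, n = NA_integer_, missing = mono,
                    stringsAsFactors = FALSE)
  keep <- which(!mono)
  if (length(keep) == 0L) return(out)

  if (mode == "regression") {
    RX <- qr.resid(qc, X[, keep, drop = FALSE])
    sxx <- colSums(RX^2)
    beta <- as.vector(crossprod(RX, ry)) / sxx
    df <- n - ncol(C) - 1L
    rss <- sum(ry^2) - beta^2 * sxx
    se <- sqrt(pmax(rss, 0) / df / sxx)
    tstat <- beta / se
    pval <- 2 * pt(-abs(tstat), df)
    out$beta[keep] <- beta; out$se[keep] <- se
    out$pval[keep] <- pmax(pval, .Machine$double.xmin)
    out$n[keep] <- n
  } else {
    g <- attr(phenotypes, paste0("genetic_", trait))
    if (is.null(g)) stop_input("analytic mode requires phenotype truth attributes")
    g <- g[subset]
    n_gwas <- as.integer(n_gwas %||% n)
    set.seed(seed)
    Xk <- X[, keep, drop = FALSE]
    vx <- apply(Xk, 2L, var)
    beta_marg <- as.vector(cov(g, Xk)) / vx
    sd_resid <- sd(y - g)
    p <- eaf[keep]
    se <- sd_resid / sqrt(2 * n_gwas * p * (1 - p))
    beta <- beta_marg + rnorm(length(keep), 0, se)
    z <- beta / se
    pval <- pmax(2 * pnorm(-abs(z)), .Machine$double.xmin)
    out$beta[keep] <- beta; out$se[keep] <- se; out$pval[keep] <- pval
    out$n[keep] <- n_gwas
  }
  out
}

#' Allele-frequency-standardized GRM and kinship fixture
#'
#' Naive genetic relationship matrix on dosages,
#' A = (1/m) sum_v (x_v - 2 p_v)(x_v - 2 p_v)' / (2 p_v (1 - p_v));
#' kinship is A/2. A fixture stand-in for production kinship estimates
#' (which are an input to the pipeline, not computed by it). With
#' `pop_freqs`, each individual is standardized by their own
#' ancestry-specific expected frequency (2 Q P'), which removes the
#' inflation that population structure induces in the pooled-frequency
#' GRM of an admixed cohort (the role local-ancestry-aware kinship
#' estimators play on real data).
#'
#' @param genotypes A `genotype_matrix` or dosage matrix.
#' @param pop_freqs Optional m x K population frequency matrix; requires
#'   `genotypes` to carry ancestry proportions.
#' @return n x n kinship matrix.
#' @export
compute_kinship <- function(genotypes, pop_freqs = NULL) {
  X <- if (inherits(genotypes, "genotype_matrix")) genotypes$dosage else genotypes
  if (!is.null(pop_freqs)) {
    Q <- genotypes$proportions
    if (is.null(Q)) stop_input("pop_freqs given but genotypes carry no proportions")
    P <- Q %*% t(as.matrix(pop_freqs))           # n x m expected frequencies
    P <- pmin(pmax(P, 1e-6), 1 - 1e-6)
    Z <- (X - 2 * P) / sqrt(2 * P * (1 - P))
    K <- tcrossprod(Z) / ncol(X) / 2
  } else {
    p <- colMeans(X) / 2
    keep <- p > 0 & p < 1
    X <- X[, keep, drop = FALSE]; p <- p[keep]
    Z <- sweep(sweep(X, 2L, 2 * p), 2L, sqrt(2 * p * (1 - p)), "/")
    K <- tcrossprod(Z) / ncol(Z) / 2
  }
  dimnames(K) <- list(rownames(X), rownames(X))
  K
}

#' True relatedness edges of a simulated cohort
#'
#' The injected first-degree-like pairs with their theoretical kinship
#' coefficient (0.25: the pair shares one full haplotype). This is the
#' ground-truth sparse kinship input the pipeline consumes; the GRM of
#' [compute_kinship()] is the corresponding estimate.
#'
#' @param genotypes A `genotype_matrix` with injected relatedness.
#' @return data.frame id1, id2, kinship.
#' @export
true_kinship_edges <- function(genotypes) {
  np <- genotypes$relatedness_pairs %||% 0L
  ids <- rownames(genotypes$dosage)
  if (np == 0L)
    return(data.frame(id1 = character(0), id2 = character(0),
                      kinship = numeric(0)))
  data.frame(id1 = ids[2L * seq_len(np) - 1L], id2 = ids[2L * seq_len(np)],
             kinship = 0.25, stringsAsFactors = FALSE)
}

#' Sparse kinship edge list
#'
#' @param kinship Square kinship matrix.
#' @param min_kinship Pairs at or below this value are dropped (sparsity).
#' @return data.frame id1, id2, kinship (upper triangle only).
#' @export
kinship_edges <- function(kinship, min_kinship = 2^-6) {
  ut <- upper.tri(kinship)
  idx <- which(ut & kinship > min_kinship, arr.ind = TRUE)
  data.frame(id1 = rownames(kinship)[idx[, 1L]],
             id2 = colnames(kinship)[idx[, 2L]],
             kinship = kinship[idx], stringsAsFactors = FALSE)
}

#' Simulate a complete multi-ancestry cohort
#'
#' Convenience driver chaining ancestral frequencies, Balding-Nichols
#' population frequencies, admixed genotypes, causal effects, phenotypes
#' and kinship under one configuration. Admixture: each individual's
#' majority component is their own group's ancestry with a Dirichlet-like
#' minority share from the others.
#'
#' @param config A [cohort_config()].
#' @return List of class `sim_cohort` with elements `genotypes`,
#'   `phenotypes`, `causal_effects`, `pop_freqs`, `ancestral_freqs`,
#'   `kinship` and `config`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  labs <- vapply(config$ancestries, `[[`, character(1), "name")
  K <- length(labs)
  anc <- simulate_ancestral_frequencies(config$m_variants, config$freq_range,
                                        seed = derive_seed(config$seed, 1L))
  pop_freqs <- sapply(seq_len(K), function(k)
    simulate_population_frequencies(anc, config$ancestries[[k]]$fst,
                                    seed = derive_seed(config$seed, 1L + k)))
  colnames(pop_freqs) <- labs

  set.seed(derive_seed(config$seed, 7L))
  n_vec <- config$n_per_group[labs]
  n <- sum(n_vec)
  group <- rep(labs, times = n_vec)
  # ~85% own ancestry, remainder split over the others with jitter
  Q <- matrix(runif(n * K, 0, 0.15 / max(K - 1, 1)), n, K,
              dimnames = list(NULL, labs))
  own <- match(group, labs)
  Q[cbind(seq_len(n), own)] <- 0
  Q[cbind(seq_len(n), own)] <- 1 - rowSums(Q)
  genotypes <- simulate_genotypes(pop_freqs, Q,
                                  ld_block_size = config$ld_block_size,
                                  ld_rho = config$ld_rho,
                                  relatedness_pairs = config$relatedness_pairs,
                                  pos_spacing = config$pos_spacing,
                                  seed = derive_seed(config$seed, 8L))
  effects <- simulate_causal_effects(config)
  phenotypes <- simulate_phenotypes(genotypes, effects, config, group = group)
  structure(list(genotypes = genotypes, phenotypes = phenotypes,
                 causal_effects = effects, pop_freqs = pop_freqs,
                 ancestral_freqs = anc,
                 kinship_edges = true_kinship_edges(genotypes),
                 config = config),
            class = "sim_cohort")
}
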