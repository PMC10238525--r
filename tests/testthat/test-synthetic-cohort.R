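# Cohort simulator: frequency models, genotypes, phenotypes, GWAS
# summary statistics, kinship.

test_that("ancestral frequencies: degenerate interval, determinism, moments", {
  expect_equal(simulate_ancestral_frequencies(5, c(0.3, 0.3), seed = 1),
               rep(0.3, 5))
  expect_identical(simulate_ancestral_frequencies(100, seed = 9),
                   simulate_ancestral_frequencies(100, seed = 9))
  # uniform on [0.05, 0.95]: mean 0.5, sd = 0.9/sqrt(12)
  p <- simulate_ancestral_frequencies(1e4, c(0.05, 0.95), seed = 2)
  se <- 0.9 / sqrt(12) / sqrt(1e4)
  expect_lt(abs(mean(p) - 0.5), 3 * se)
  expect_error(simulate_ancestral_frequencies(10, c(0.9, 0.1)),
               class = "multiprs_config_error")
  expect_error(simulate_ancestral_frequencies(10, c(0, 0.5)),
               class = "multiprs_config_error")
})

test_that("Balding-Nichols draws have the Beta mean and variance", {
  anc <- rep(0.4, 1e4)
  # near-zero divergence: population tracks the ancestral pool
  p_small <- simulate_population_frequencies(anc, 1e-6, seed = 3)
  expect_lt(max(abs(p_small - 0.4)), 1e-2)
  # mean p, variance F p (1 - p), each within 3 SE over 1e4 draws
  p <- simulate_population_frequencies(anc, 0.2, seed = 4)
  v_true <- 0.2 * 0.4 * 0.6
  expect_lt(abs(mean(p) - 0.4), 3 * sqrt(v_true / 1e4))
  # SE of a sample variance ~ sqrt((mu4 - v^2)/n); bound with 3*v*sqrt(3/n)
  expect_lt(abs(var(p) - v_true), 3 * v_true * sqrt(3 / 1e4))
  expect_true(all(p > 0 & p < 1))
  expect_error(simulate_population_frequencies(anc, 1.2),
               class = "multiprs_config_error")
})

test_that("genotype simulation: fixed alleles, sampling, LD structure", {
  n <- 400L
  Q <- matrix(1, n, 1)
  # fixed allele: p = 1 gives dosage 2 everywhere
  g_fix <- simulate_genotypes(matrix(c(1 - 1e-12, 0.5), ncol = 1), Q[1:50, , drop = FALSE],
                              ld_block_size = 1L, seed = 5)
  expect_true(all(g_fix$dosage[, 1] == 2))
  # binomial sampling: sample frequency within 3 SE of p
  pf <- matrix(runif(50, 0.2, 0.8), ncol = 1)
  g <- simulate_genotypes(pf, Q, ld_block_size = 1L, seed = 6)
  expect_true(all(g$dosage %in% 0:2))
  freq <- colMeans(g$dosage) / 2
  se <- sqrt(pf[, 1] * (1 - pf[, 1]) / (2 * n))
  expect_true(all(abs(freq - pf[, 1]) < 3.5 * se))
  # block size 1: off-diagonal r^2 consistent with independence (E[r^2] ~ 1/n)
  r2 <- cor(g$dosage)^2
  off <- r2[upper.tri(r2)]
  expect_lt(mean(off), 1 / n + 3 * sqrt(2) / n)
  # blocks: within-block r^2 exceeds between-block r^2
  gb <- simulate_genotypes(pf, Q, ld_block_size = 5L, ld_rho = 0.8, seed = 7)
  r2b <- cor(gb$dosage)^2
  blk <- rep(seq_len(10), each = 5)
  same <- outer(blk, blk, "==") & upper.tri(r2b)
  diff <- outer(blk, blk, "!=") & upper.tri(r2b)
  expect_gt(mean(r2b[same]), 10 * mean(r2b[diff]))
  expect_error(simulate_genotypes(pf, matrix(c(0.6, 0.6), 1, 2)),
               class = "multiprs_input_error")
})

test_that("frequency divergence increases monotonically in FST", {
  anc <- simulate_ancestral_frequencies(2000, seed = 8)
  div <- sapply(c(0.01, 0.05, 0.2), function(f) {
    p1 <- simulate_population_frequencies(anc, f, seed = 21)
    p2 <- simulate_population_frequencies(anc, f, seed = 22)
    mean(abs(p1 - p2))
  })
  expect_true(all(diff(div) > 0))
})

test_that("phenotypes: noise-only limit, infeasible config, heritability", {
  cc0 <- cohort_config(n_per_group = c(EUR = 2000L, AFR = 2000L, EAS = 100L),
                       m_variants = 50L, m_causal = 10L,
                       heritability_prs = 0,
                       covariate_effects = list(age = 0, age2 = 0, sex = 0,
                                                bmi = 0, smoking_current = 0),
                       med_use_prob = c(EUR = 0, AFR = 0, EAS = 0),
                       seed = 31L)
  co0 <- simulate_cohort(cc0)
  ph0 <- co0$phenotypes
  for (gp in c("EUR", "AFR")) {
    s <- sd(ph0$sbp[ph0$group == gp] - 120)
    sd_true <- cc0$group_residual_sd_sbp[gp]
    n_g <- sum(ph0$group == gp)
    expect_lt(abs(s - sd_true), 3 * sd_true / sqrt(2 * n_g))
  }
  # residual-variance ratio between groups recovered within 10%
  ratio <- var(ph0$sbp[ph0$group == "AFR"]) / var(ph0$sbp[ph0$group == "EUR"])
  expect_lt(abs(ratio / (19 / 17)^2 - 1), 0.10)

  # contradiction: positive heritability with all-zero effects
  cc <- cohort_config(seed = 32L)
  co <- simulate_cohort(cc)
  zero_eff <- list(sbp = numeric(cc$m_variants), dbp = numeric(cc$m_variants))
  expect_error(simulate_phenotypes(co$genotypes, zero_eff, cc),
               class = "multiprs_config_error")

  # R^2 of the covariate-free trait on the true genetic value ~ h2
  cc1 <- cohort_config(n_per_group = c(EUR = 5000L, AFR = 100L, EAS = 100L),
                       m_variants = 200L, m_causal = 40L,
                       heritability_prs = 0.10,
                       covariate_effects = list(age = 0, age2 = 0, sex = 0,
                                                bmi = 0, smoking_current = 0),
                       med_use_prob = c(EUR = 0, AFR = 0, EAS = 0),
                       seed = 33L)
  co1 <- simulate_cohort(cc1)
  g <- attr(co1$phenotypes, "genetic_sbp")
  r2 <- summary(lm(co1$phenotypes$sbp ~ g))$r.squared
  expect_lt(abs(r2 - 0.10), 0.02)
})

test_that("simulated GWAS: null p-values uniform, modes agree, monomorphic flagged", {
  # fixed genotype, replicate pure-noise traits: null p-values are uniform
  set.seed(41)
  nrep <- 500L; n <- 150L
  pf <- matrix(c(0.5, 0.3, 0.7), ncol = 1)
  Q1 <- matrix(1, n, 1)
  pvals <- replicate(nrep, {
    g <- simulate_genotypes(pf, Q1, ld_block_size = 1L,
                            seed = sample.int(1e6, 1))
    ph <- data.frame(id = rownames(g$dosage), age = runif(n, 30, 70),
                     sex = rbinom(n, 1, 0.5), bmi = rnorm(n, 28, 4),
                     smoking = "never", sbp = rnorm(n, 120, 15),
                     dbp = rnorm(n, 75, 10))
    simulate_gwas_sumstats(g, ph, trait = "sbp", seed = 1)$pval[1]
  })
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)

  # regression and analytic modes agree on the mean effect estimate
  co <- tiny_cohort(seed = 42L, n_eur = 2000L, n_afr = 100L, m = 100L, h2 = 0.3)
  sub <- which(co$phenotypes$group == "EUR")
  reg <- simulate_gwas_sumstats(co$genotypes, co$phenotypes, sub, "sbp",
                                mode = "regression")
  ana <- simulate_gwas_sumstats(co$genotypes, co$phenotypes, sub, "sbp",
                                mode = "analytic", n_gwas = 2000L, seed = 5)
  ok <- !reg$missing & !ana$missing
  d <- reg$beta[ok] - ana$beta[ok]
  pooled_se <- sqrt(reg$se[ok]^2 + ana$se[ok]^2)
  expect_lt(abs(mean(d / pooled_se)), 3 / sqrt(sum(ok)) * 3)

  # monomorphic variant: flagged missing, not an error
  g <- co$genotypes
  g$dosage[, 1] <- 2L
  ss <- simulate_gwas_sumstats(g, co$phenotypes, sub, "sbp")
  expect_true(ss$missing[1])
  expect_true(is.na(ss$beta[1]))
})

test_that("cohort generation is deterministic under a fixed seed", {
  a <- tiny_cohort(seed = 77L, n_eur = 100L, n_afr = 80L, m = 60L)
  b <- tiny_cohort(seed = 77L, n_eur = 100L, n_afr = 80L, m = 60L)
  expect_identical(a$genotypes$dosage, b$genotypes$dosage)
  expect_identical(a$phenotypes, b$phenotypes)
})

test_that("injected relatedness is recovered by the fixture GRM", {
  co <- tiny_cohort(seed = 51L, n_eur = 200L, n_afr = 150L, m = 400L,
                    rel_pairs = 8L)
  K <- compute_kinship(co$genotypes, co$pop_freqs)
  te <- true_kinship_edges(co$genotypes)
  expect_equal(nrow(te), 8L)
  rel_k <- K[cbind(te$id1, te$id2)]
  expect_true(all(rel_k > 2^-4.5))
  # unrelated pairs sit below the threshold on average
  mask <- upper.tri(K)
  mask[cbind(match(te$id1, rownames(K)), match(te$id2, colnames(K)))] <- FALSE
  expect_lt(mean(K[mask]), 2^-4.5)
})
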