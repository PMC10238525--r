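# LD clumping, thresholding, scoring and standardization.

# dosage panel with two variants at controlled correlation
two_snp_panel <- function(r_target, n = 400L, seed = 2L) {
  set.seed(seed)
  x1 <- rbinom(n, 2L, 0.5)
  flip <- runif(n) > abs(r_target)
  x2 <- ifelse(flip, rbinom(n, 2L, 0.5), x1)
  ids <- variant_id("1", c(1000, 11000), "G", "A")
  X <- cbind(x1, x2)
  colnames(X) <- ids
  rownames(X) <- paste0("i", seq_len(n))
  structure(list(dosage = X,
                 variants = data.frame(id = ids, chrom = "1",
                                       pos = c(1000, 11000),
                                       other_allele = "G", effect_allele = "A",
                                       stringsAsFactors = FALSE),
                 proportions = NULL),
            class = "genotype_matrix")
}

two_snp_ss <- function(pvals) {
  data.frame(chrom = "1", pos = c(1000, 11000), effect_allele = "A",
             other_allele = "G", beta = c(0.5, 0.4), se = 0.01,
             pval = pvals, eaf = 0.5, n = 1000, stringsAsFactors = FALSE)
}

test_that("clumping keeps the stronger of a correlated pair, both when independent", {
  g_hi <- two_snp_panel(0.9)
  r2_hi <- cor(g_hi$dosage[, 1], g_hi$dosage[, 2])^2
  expect_gt(r2_hi, 0.5)
  ss <- two_snp_ss(c(1e-9, 1e-8))
  got <- ld_clump(ss, g_hi, clump_params(p_threshold = 5e-8))
  expect_equal(got, variant_id("1", 1000, "G", "A"))

  g_lo <- two_snp_panel(0.1, seed = 3L)
  expect_lt(cor(g_lo$dosage[, 1], g_lo$dosage[, 2])^2, 0.1)
  got2 <- ld_clump(ss, g_lo, clump_params(p_threshold = 5e-8))
  expect_setequal(got2, variant_id("1", c(1000, 11000), "G", "A"))

  # single variant below threshold
  got3 <- ld_clump(ss[1, ], g_hi, clump_params(p_threshold = 5e-8))
  expect_equal(got3, variant_id("1", 1000, "G", "A"))
  # nothing passes: empty with warning
  expect_warning(got4 <- ld_clump(two_snp_ss(c(0.5, 0.9)), g_hi,
                                  clump_params(p_threshold = 5e-8)))
  expect_length(got4, 0L)
})

test_that("clumping equals the exhaustive brute-force oracle on random instances", {
  for (s in 1:25) {
    inst <- random_clump_instance(1000 + s)
    pars <- clump_params(r2_max = 0.1, window_kb = 1000, p_threshold = 0.5)
    got <- ld_clump(inst$sumstats, inst$genotypes, pars)
    exp <- oracle_clump(inst$sumstats, inst$genotypes$dosage, 0.1, 1000, 0.5)
    expect_identical(sort(got), sort(exp))
    # post-hoc invariant: no retained pair is both close and correlated
    ss <- inst$sumstats
    ids <- variant_id(ss$chrom, ss$pos, ss$other_allele, ss$effect_allele)
    kept <- match(got, ids)
    if (length(kept) > 1L) {
      X <- inst$genotypes$dosage[, kept, drop = FALSE]
      for (a in seq_along(kept)[-1]) for (b in seq_len(a - 1L)) {
        ia <- kept[a]; ib <- kept[b]
        if (ss$chrom[ia] == ss$chrom[ib] &&
            abs(ss$pos[ia] - ss$pos[ib]) <= 1e6 &&
            sd(X[, a]) > 0 && sd(X[, b]) > 0)
          expect_lte(cor(X[, a], X[, b])^2, 0.1)
      }
    }
  }
})

test_that("threshold_weights nests across thresholds and handles edge cases", {
  inst <- random_clump_instance(7, max_m = 40)
  idx <- ld_clump(inst$sumstats, inst$genotypes, clump_params(p_threshold = 1))
  strict <- threshold_weights(inst$sumstats, idx, 1e-2)
  loose <- threshold_weights(inst$sumstats, idx, 1)
  expect_true(all(strict$variant_id %in% loose$variant_id))
  expect_equal(loose$weight,
               inst$sumstats$beta[match(loose$variant_id,
                                        variant_id(inst$sumstats$chrom,
                                                   inst$sumstats$pos,
                                                   inst$sumstats$other_allele,
                                                   inst$sumstats$effect_allele))])
  expect_equal(nrow(threshold_weights(inst$sumstats, character(0), 1)), 0L)
})

test_that("scoring is the weighted dosage sum with EAF imputation of missing", {
  ids <- variant_id("1", 1:5 * 10, "G", "A")
  X <- matrix(c(0, 1, 2, 1,
                2, 2, 0, 0,
                1, 1, 1, 1,
                0, 0, 0, 2,
                NA, 1, 0, 1), 4, 5,
              dimnames = list(paste0("i", 1:4), ids))
  wt <- data.frame(variant_id = ids, chrom = "1", pos = 1:5 * 10,
                   effect_allele = "A", other_allele = "G",
                   weight = c(0.5, -1, 0.25, 2, 1), source = "x",
                   stringsAsFactors = FALSE)
  # hand oracle: impute the NA as mean of observed dosage = 2 x EAF
  Ximp <- X; Ximp[1, 5] <- mean(X[2:4, 5])
  expect_equal(score_prs(X, wt), drop(Ximp %*% wt$weight), ignore_attr = TRUE)

  # zero weights score zero; simple arithmetic on one variant
  wt0 <- wt; wt0$weight <- 0
  expect_equal(unname(score_prs(X, wt0)), rep(0, 4), ignore_attr = TRUE)
  wt1 <- wt[3, ]; wt1$weight <- 0.5
  expect_equal(unname(score_prs(X[, 3, drop = FALSE], wt1)), rep(0.5, 4),
               ignore_attr = TRUE)

  # absent variants dropped (counted) or an error in strict mode
  wt_extra <- rbind(wt, data.frame(variant_id = variant_id("2", 999, "G", "A"),
                                   chrom = "2", pos = 999, effect_allele = "A",
                                   other_allele = "G", weight = 3, source = "x"))
  sc <- score_prs(X, wt_extra)
  expect_equal(attr(sc, "n_dropped"), 1L)
  expect_error(score_prs(X, wt_extra, strict = TRUE),
               class = "multiprs_input_error")
})

test_that("standardization: reference self-standardizes; degenerate errors; AF shift", {
  set.seed(4)
  raw <- rnorm(100, 5, 3)
  sp <- standardize_prs(raw)
  expect_lt(abs(mean(sp$score)), 1e-12)
  expect_lt(abs(sd(sp$score) - 1), 1e-12)
  expect_error(standardize_prs(rep(1, 10)), class = "multiprs_numeric_error")

  # a cohort with shifted allele frequencies gets a nonzero mean whose sign
  # matches the sum of weight x 2 x frequency shift
  anc <- simulate_ancestral_frequencies(200, seed = 5)
  pA <- simulate_population_frequencies(anc, 0.01, seed = 6)
  pB <- simulate_population_frequencies(anc, 0.2, seed = 7)
  gA <- simulate_genotypes(matrix(pA, ncol = 1), matrix(1, 500, 1),
                           ld_block_size = 1L, seed = 8)
  gB <- simulate_genotypes(matrix(pB, ncol = 1), matrix(1, 500, 1),
                           ld_block_size = 1L, seed = 9)
  colnames(gB$dosage) <- colnames(gA$dosage)
  set.seed(10)
  wt <- data.frame(variant_id = colnames(gA$dosage),
                   chrom = gA$variants$chrom, pos = gA$variants$pos,
                   effect_allele = gA$variants$effect_allele,
                   other_allele = gA$variants$other_allele,
                   weight = rnorm(200, 0, 0.3), source = "x",
                   stringsAsFactors = FALSE)
  rawA <- score_prs(gA, wt); rawB <- score_prs(gB, wt)
  spA <- standardize_prs(rawA, ref_id = "cohortA")
  spB <- standardize_prs(rawB, reference = spA)
  pred_shift <- sum(wt$weight * 2 * (pB - pA)) / spA$ref_sd
  se_shift <- sd(spB$score) / sqrt(500) * 3 + abs(pred_shift) * 0.25
  expect_equal(sign(mean(spB$score)), sign(pred_shift))
  expect_lt(abs(mean(spB$score) - pred_shift), 3 * se_shift)
})

test_that("weight tables round-trip through TSV and PLINK score format", {
  ids <- variant_id("1", c(10, 20), c("G", "T"), c("A", "C"))
  wt <- data.frame(variant_id = ids, chrom = "1", pos = c(10, 20),
                   effect_allele = c("A", "C"), other_allele = c("G", "T"),
                   weight = c(0.12, -0.4), source = "demo",
                   stringsAsFactors = FALSE)
  class(wt) <- c("weight_table", "data.frame")
  f <- tempfile(fileext = ".tsv")
  write_weight_table(wt, f)
  got <- read_weight_table(f)
  expect_equal(got$weight, wt$weight)
  expect_equal(got$effect_allele, wt$effect_allele)
  expect_equal(got$pos, wt$pos)

  # 3-column headerless PLINK --score layout
  f2 <- tempfile(fileext = ".txt")
  writeLines(c("1:10:G:A\tA\t0.12", "1:20:T:C\tC\t-0.4"), f2)
  got2 <- read_weight_table(f2, source = "plink")
  expect_equal(got2$weight, wt$weight)
  expect_equal(got2$other_allele, wt$other_allele)
})
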