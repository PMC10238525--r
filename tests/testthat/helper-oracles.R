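# Independent brute-force oracles and small fixture builders shared across
# test files. Oracles re-derive expected results from first principles and
# never call the implementation paths they check.

# Exhaustive greedy clumping oracle: re-scan every remaining pair at each
# step, compute r^2 directly from the panel dosages.
oracle_clump <- function(sumstats, dosage, r2_max, window_kb, p_threshold) {
  keep <- which(!is.na(sumstats$pval) & sumstats$pval <= p_threshold)
  ss <- sumstats[keep, , drop = FALSE]
  X <- dosage[, keep, drop = FALSE]
  alive <- rep(TRUE, nrow(ss))
  chosen <- integer(0)
  while (any(alive)) {
    cand <- which(alive)
    o <- cand[order(ss$pval[cand], ss$chrom[cand], ss$pos[cand])]
    i <- o[1L]
    chosen <- c(chosen, i)
    alive[i] <- FALSE
    for (j in which(alive)) {
      if (ss$chrom[j] != ss$chrom[i]) next
      if (abs(ss$pos[j] - ss$pos[i]) > window_kb * 1000) next
      if (sd(X[, i]) == 0 || sd(X[, j]) == 0) next
      if (cor(X[, i], X[, j])^2 > r2_max) alive[j] <- FALSE
    }
  }
  paste(ss$chrom[chosen], ss$pos[chosen], ss$other_allele[chosen],
        ss$effect_allele[chosen], sep = ":")
}

# Greedy unrelated-selection oracle with the same tie rule (max degree,
# then lexicographically larger id), recomputing degrees from scratch.
oracle_unrelated <- function(edges, ids, threshold) {
  e <- edges[edges$kinship > threshold, , drop = FALSE]
  all_ids <- unique(c(ids, edges$id1, edges$id2))
  dropped <- character(0)
  repeat {
    if (nrow(e) == 0L) break
    deg <- sapply(all_ids, function(i) sum(e$id1 == i) + sum(e$id2 == i))
    deg <- deg[deg > 0]
    mx <- names(deg)[deg == max(deg)]
    victim <- sort(mx, decreasing = TRUE)[1L]
    dropped <- c(dropped, victim)
    e <- e[e$id1 != victim & e$id2 != victim, , drop = FALSE]
  }
  sort(setdiff(all_ids, dropped))
}

# All-pairs Mann-Whitney AUC with ties counted one half.
oracle_auc <- function(outcome, score) {
  cases <- score[outcome == 1]
  ctrls <- score[outcome == 0]
  tot <- 0
  for (a in cases) for (b in ctrls)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cases) * length(ctrls))
}

# A tiny two-ancestry cohort used by several files.
tiny_cohort <- function(seed = 11L, n_eur = 250L, n_afr = 150L,
                        m = 300L, h2 = 0.1, rel_pairs = 0L) {
  cohort_config(
    ancestries = list(ancestry_spec("EUR", 0.05, 20000L),
                      ancestry_spec("AFR", 0.15, 10000L)),
    n_per_group = c(EUR = n_eur, AFR = n_afr),
    m_variants = m, m_causal = max(10L, m %/% 10L),
    heritability_prs = h2,
    group_residual_sd_sbp = c(EUR = 17, AFR = 19),
    group_residual_sd_dbp = c(EUR = 10, AFR = 11.18),
    med_use_prob = c(EUR = 0.25, AFR = 0.25),
    relatedness_pairs = rel_pairs, seed = seed) |>
    simulate_cohort()
}

# Random clumping instance: n_panel individuals, <= max_m variants with
# block LD, random p-values (occasionally tied), 1-2 chromosomes.
random_clump_instance <- function(seed, max_m = 60L, n_panel = 200L) {
  set.seed(seed)
  m <- sample(5:max_m, 1L)
  k <- 2L
  anc <- runif(m, 0.1, 0.9)
  pf <- cbind(A = anc, B = pmin(pmax(anc + rnorm(m, 0, 0.1), 0.02), 0.98))
  Q <- cbind(runif(n_panel), 0); Q[, 2] <- 1 - Q[, 1]
  g <- simulate_genotypes(pf, Q, ld_block_size = sample(c(1L, 4L, 8L), 1L),
                          ld_rho = runif(1, 0.3, 0.95),
                          chrom = c("1", "2")[seq_len(sample(1:2, 1L))],
                          pos_spacing = sample(c(500L, 5000L, 400000L), 1L),
                          seed = seed + 1L)
  pv <- signif(runif(m)^2, 3)                 # signif() injects ties
  ss <- data.frame(chrom = g$variants$chrom, pos = g$variants$pos,
                   effect_allele = g$variants$effect_allele,
                   other_allele = g$variants$other_allele,
                   beta = rnorm(m), se = runif(m, 0.01, 0.1), pval = pv,
                   eaf = colMeans(g$dosage) / 2, n = n_panel,
                   stringsAsFactors = FALSE)
  list(sumstats = ss, genotypes = g)
}
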