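# Summary-statistic reading, QC filtering and allele harmonization.

make_ss <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(chrom = r[[1]], pos = as.numeric(r[[2]]),
               effect_allele = r[[3]], other_allele = r[[4]],
               beta = as.numeric(r[[5]]), se = as.numeric(r[[6]]),
               pval = as.numeric(r[[7]]), eaf = as.numeric(r[[8]]),
               n = 1000, stringsAsFactors = FALSE)))
}

write_ss_file <- function(ss, path, names_map = NULL) {
  if (!is.null(names_map)) names(ss)[match(names(names_map), names(ss))] <- names_map
  write.table(ss, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("read_sumstats parses, drops malformed rows, honors column_map", {
  ss <- make_ss(list("1", 100, "A", "G", 0.2, 0.05, 1e-4, 0.3),
                list("1", 200, "C", "T", -0.1, 0.04, 0.5, 0.6),
                list("2", 300, "G", "A", 0.05, 0.03, 0.9, 0.1))
  f <- tempfile(fileext = ".tsv")
  expect_equal(nrow(read_sumstats(write_ss_file(ss, f))), 3L)

  # pval = 0 is outside (0, 1]: dropped with a count
  ss_bad <- ss; ss_bad$pval[2] <- 0
  suppressMessages(got <- read_sumstats(write_ss_file(ss_bad, f)))
  expect_equal(nrow(got), 2L)
  expect_equal(attr(got, "n_dropped"), 1L)

  # alternate header resolved through column_map gives identical records
  f2 <- tempfile(fileext = ".tsv")
  write_ss_file(ss, f2, names_map = c(chrom = "CHR", pos = "BP", pval = "P"))
  got2 <- read_sumstats(f2, column_map = c(chrom = "CHR", pos = "BP", pval = "P"))
  expect_equal(got2, read_sumstats(write_ss_file(ss, f)),
               ignore_attr = TRUE)

  expect_error(read_sumstats(f2), class = "multiprs_input_error")
  expect_error(read_sumstats("/nonexistent.tsv"),
               class = "multiprs_input_error")
})

test_that("qc_filter applies the MAF and missingness rules", {
  ss <- make_ss(list("1", 100, "A", "G", 0.2, 0.05, 1e-4, 0.5),
                list("1", 200, "C", "T", -0.1, 0.04, 0.5, 0.5))
  pf <- c("1:100" = 0.005, "1:200" = 0.3)
  got <- qc_filter(ss, pf)
  expect_equal(got$pos, 200)            # panel MAF 0.005 < 0.01 removed
  expect_equal(unname(attr(got, "report")["removed_maf"]), 1L)

  # missingness >= 1% removes; report partitions the input
  pf2 <- c("1:100" = 0.4, "1:200" = 0.3)
  pm <- c("1:100" = 0.02, "1:200" = 0)
  got2 <- qc_filter(ss, pf2, pm)
  expect_equal(got2$pos, 200)
  rep2 <- attr(got2, "report")
  expect_equal(unname(rep2["input"]),
               unname(rep2["removed_maf"] + rep2["removed_missingness"] +
                        rep2["retained"]))
})

test_that("qc_filter matches a brute-force filter on a crafted panel", {
  set.seed(3)
  ss <- make_ss(list("1", 1, "A", "G", 1, 1, 0.5, 0.5),
                list("1", 2, "A", "G", 1, 1, 0.5, 0.005),
                list("1", 3, "A", "G", 1, 1, 0.5, 0.995),
                list("1", 4, "A", "G", 1, 1, 0.5, 0.2),
                list("1", 5, "A", "G", 1, 1, 0.5, 0.3),
                list("1", 6, "A", "G", 1, 1, 0.5, 0.6))
  key <- paste("1", 1:6, sep = ":")
  pf <- setNames(c(0.5, 0.5, 0.5, 0.002, 0.999, 0.4), key)
  pm <- setNames(c(0, 0.05, 0, 0, 0, 0.009), key)
  expected <- which(pmin(ss$eaf, 1 - ss$eaf) >= 0.01 &
                      pmin(pf, 1 - pf) >= 0.01 & pm < 0.01)
  got <- qc_filter(ss, pf, pm)
  expect_equal(got$pos, ss$pos[expected])
})

panel <- data.frame(chrom = "1", pos = c(100, 200, 300),
                    other_allele = c("G", "T", "T"),
                    effect_allele = c("A", "C", "G"),
                    stringsAsFactors = FALSE)

test_that("harmonize_alleles removes ambiguous pairs and flips swapped records", {
  ss <- make_ss(list("1", 100, "A", "T", 0.3, 0.1, 1e-3, 0.4),   # ambiguous A/T
                list("1", 200, "G", "C", 0.3, 0.1, 1e-3, 0.4),   # ambiguous C/G
                list("1", 300, "T", "G", 0.2, 0.1, 1e-3, 0.3),   # swapped vs panel
                list("1", 400, "A", "G", 0.1, 0.1, 1e-3, 0.2))   # not in panel
  got <- harmonize_alleles(ss, panel)
  rep <- attr(got, "report")
  expect_equal(unname(rep["removed_ambiguous"]), 2L)
  expect_equal(unname(rep["unmatched"]), 1L)
  expect_equal(nrow(got), 1L)
  # swapped: beta negated, eaf complemented, alleles now panel-coded
  expect_equal(got$beta, -0.2)
  expect_equal(got$eaf, 0.7)
  expect_equal(got$effect_allele, "G")
  expect_equal(got$other_allele, "T")
  expect_true(got$flipped)
  # counts partition the input
  expect_equal(unname(rep["input"]),
               unname(rep["removed_ambiguous"] + rep["unmatched"] +
                        rep["retained"]))
})

test_that("harmonization is idempotent and rejects conflicting duplicates", {
  ss <- make_ss(list("1", 200, "T", "C", 0.2, 0.1, 1e-3, 0.3),
                list("1", 300, "G", "T", -0.5, 0.1, 1e-3, 0.8))
  once <- harmonize_alleles(ss, panel)
  twice <- harmonize_alleles(once[, names(ss)], panel)
  expect_equal(twice$beta, once$beta)
  expect_equal(twice$eaf, once$eaf)
  expect_equal(twice$effect_allele, once$effect_allele)
  expect_false(any(twice$flipped))

  dup_panel <- rbind(panel, data.frame(chrom = "1", pos = 100,
                                       other_allele = "T", effect_allele = "C"))
  expect_error(harmonize_alleles(ss, dup_panel), class = "multiprs_input_error")
  ss_dup <- rbind(ss, ss[1, ])
  expect_error(harmonize_alleles(ss_dup, panel), class = "multiprs_input_error")
})

test_that("allele-swapped weights give identical standardized PRS", {
  # allele-coding symmetry: a swapped, beta-negated record scores to a
  # per-variant additive constant, absorbed by standardization
  set.seed(9)
  dos <- matrix(rbinom(40, 2, 0.4), 8, 5,
                dimnames = list(paste0("i", 1:8),
                                variant_id("1", 1:5 * 100, "G", "A")))
  wt <- data.frame(variant_id = colnames(dos), chrom = "1", pos = 1:5 * 100,
                   effect_allele = "A", other_allele = "G",
                   weight = rnorm(5), source = "x", stringsAsFactors = FALSE)
  raw1 <- score_prs(dos, wt)
  dos_sw <- 2 - dos                        # count the other allele
  wt_sw <- wt; wt_sw$weight <- -wt$weight
  raw2 <- score_prs(dos_sw, wt_sw)
  expect_equal(raw2 - raw1, rep(-sum(2 * wt$weight), 8), ignore_attr = TRUE)
  expect_equal(standardize_prs(raw1)$score, standardize_prs(raw2)$score,
               tolerance = 1e-12)
})
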