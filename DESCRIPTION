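Package: multiprs
Title: Construction, Combination and Evaluation of Blood-Pressure Polygenic
    Risk Scores Across Population Groups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating polygenic risk scores (PRS) for
    quantitative blood-pressure traits in multi-ancestry cohorts: harmonization
    and quality control of GWAS summary statistics against a genotype panel,
    clump-and-threshold PRS construction with an LD reference panel, additive
    scoring and reference-cohort standardization, unweighted and
    regression-weighted multi-PRS combination with weights trained in an
    independent cohort, phenotype preparation (antihypertensive-medication
    adjustment, stratum labels, kinship-based unrelated-subset selection),
    association models with group-specific intercepts and heterogeneous
    residual variances, percent-variance-explained (PVE) evaluation with
    percentile-bootstrap confidence intervals, rank-based AUC for binary
    outcomes, and ancestry-specific allele-frequency diagnostics. Includes a
    multi-ancestry cohort simulator (Balding-Nichols allele-frequency
    divergence, block LD, admixture, polygenic phenotypes with group-specific
    residual variances, relatedness, per-population GWAS summary statistics)
    so the full pipeline can be exercised without access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    vcfR
Config/testthat/edition: 3
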