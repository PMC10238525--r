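# multiprs

Construction, combination and evaluation of polygenic risk scores (PRS)
for blood-pressure traits across population groups.

## What this package is for

Polygenic risk scores for systolic and diastolic blood pressure (SBP,
DBP) are built from GWAS effect estimates, but the available GWAS differ
in ancestry composition and size, and PRS performance differs
systematically across population groups. Analysts evaluating BP PRSs in
a multi-ancestry cohort need a reproducible chain covering:

- **Summary-statistic harmonization**: allele flipping, removal of
  strand-ambiguous (A/T, C/G) variants, MAF ≥ 0.01 and missingness < 1%
  QC against the target genotype panel.
- **Clump-and-threshold construction**: greedy LD clumping
  (r² = 0.1, 1000 kb window) at p-value thresholds
  {5×10⁻⁸, 10⁻⁵, 10⁻²}, additive dosage scoring, and standardization to
  mean 0 / variance 1 in a reference cohort. Externally computed weight
  tables (Bayesian shrinkage methods) are consumed through the same
  container.
- **Multi-PRS combination**: the unweighted sum
  PRS₁ + PRS₂ + ⋯ and the weighted sum w₁PRS₁ + w₂PRS₂ + ⋯, with
  weights trained as the coefficients of a joint regression in an
  independent cohort; optional cross-dataset `scale` / `scale+match`
  (quantile-mapping) harmonization.
- **Evaluation**: linear models with group-specific intercepts and
  heterogeneous residual variances (FGLS), an optional kinship random
  effect, and percent variance explained

  PVE = (1 − σ̂²_prs / σ̂²_null) × 100%,

  computed on unrelated individuals (kinship threshold
  2⁻⁴·⁵ ≈ 4.4%), with 95% percentile-bootstrap confidence intervals and
  stratified runs by age band (≤40 / 40–60 / >60), sex, obesity
  (BMI ≥ 30) and medication use. Rank-based (Mann–Whitney) AUC for
  binary outcomes.
- **Preparation**: the standard antihypertensive-medication adjustment
  (+15 mmHg SBP, +10 mmHg DBP in medication users) and greedy
  unrelated-subset selection from a sparse kinship graph.
- **Ancestry diagnostics**: ancestry-specific allele frequencies
  estimated from dosages and global admixture proportions
  (box-constrained least squares), ≥80%-ancestry grouping, and
  effect-size-versus-frequency profiles.

Because the cohorts such analyses run on are access-restricted, the
package includes a full synthetic multi-ancestry cohort generator
(Balding–Nichols allele-frequency divergence, block LD, admixture,
polygenic phenotypes with group-specific residual variances, injected
relatedness, simulated per-population GWAS summary statistics) so the
entire pipeline is testable with known ground truth. See the methods
vignette (`vignettes/multiprs-methods.Rmd`) for the models and the
design decisions.

## Worked example

The bundled demo configuration simulates two ancestry groups
(~1200 individuals, 600 variants, 10 related pairs), simulates one GWAS
per group, builds clump-and-threshold PRSs at two thresholds, trains
combination weights on a 40% split and evaluates everything on the rest:

```r
library(multiprs)
cfg <- demo_config(seed = 42L)
res <- run_pipeline(cfg, out_dir = "demo_run")
subset(res$evaluation, stratum == "all")[, c("prs_label", "n", "beta", "se", "pval", "pve")]
```

```
    prs_label   n beta    se     pval   pve
    EUR_p0.01 720 6.24 0.684 8.18e-20 10.56
    AFR_p0.01 720 4.81 0.698 5.59e-12  6.08
      PRS_sum 720 1.83 0.195 5.55e-21 11.03
 PRS_weighted 720 1.20 0.126 1.41e-21 11.41
```

`beta` is the association of the trait (mmHg) per reference-cohort SD of
the PRS, from a model with group intercepts and age/sex/BMI adjustment;
`pve` is the percent of residual variance explained among unrelated
individuals. In this run the PRS from the larger simulated GWAS
(`EUR_p0.01`, PVE 10.6%) beats the smaller one (`AFR_p0.01`, 6.1%), and
the trained weighted sum beats both (11.4%) — the qualitative ordering
multi-PRS methods are designed to produce. `run_pipeline()` also writes
every stage's outputs with MD5 hashes and a JSON run report; re-running
the same configuration reproduces identical hashes.

Individual stages are exported directly (`read_sumstats()`,
`qc_filter()`, `harmonize_alleles()`, `ld_clump()`, `score_prs()`,
`standardize_prs()`, `train_combination_weights()`,
`adjust_for_medication()`, `select_unrelated()`, `compute_pve()`,
`bootstrap_pve_ci()`, `stratified_evaluation()`, `compute_auc()`,
`estimate_ancestry_freqs()`, …) for use outside the driver.

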