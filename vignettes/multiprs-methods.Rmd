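---
title: "Methods: constructing, combining and evaluating blood-pressure PRSs across population groups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constructing, combining and evaluating blood-pressure PRSs across population groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multiprs)
```

## Overview

`multiprs` implements the full analysis chain used to evaluate polygenic
risk scores (PRS) for quantitative blood-pressure traits — systolic (SBP)
and diastolic (DBP) pressure, in mmHg — in cohorts spanning several
population groups:

1. harmonization and quality control of GWAS summary statistics against a
   target genotype panel;
2. clump-and-threshold PRS construction against an LD reference panel;
3. additive scoring and standardization to a reference cohort;
4. unweighted and regression-weighted multi-PRS sums, with weights trained
   in an independent cohort;
5. phenotype preparation (antihypertensive-medication adjustment, stratum
   labels, kinship-based unrelated-subset selection);
6. association models with group-specific intercepts and heterogeneous
   residual variances, percent-variance-explained (PVE) evaluation with
   percentile-bootstrap confidence intervals, and rank-based AUC for
   binary outcomes;
7. ancestry diagnostics: ancestry-specific allele frequencies estimated
   from admixture proportions, majority-ancestry grouping, and the
   effect-size-versus-frequency profile.

Because the individual-level cohorts this kind of analysis runs on are
access-restricted, the package ships a first-class synthetic cohort
generator reproducing the statistical structure the evaluation relies on.
Every stage is exercised end to end on simulated data with known ground
truth.

## The synthetic cohort generator

### Genetics

Allele frequencies follow the Balding–Nichols divergence model: a shared
ancestral pool with frequencies drawn uniformly (default on
$[0.05, 0.95]$), and for each population $k$ with divergence $F_k$
(an $F_{ST}$-like parameter), per-variant frequencies

$$p_{vk} \sim \mathrm{Beta}\!\left(p_v \frac{1-F_k}{F_k},\;
  (1-p_v)\frac{1-F_k}{F_k}\right),$$

which has mean $p_v$ and variance $F_k\,p_v(1-p_v)$. Defaults use three
populations — European-like ($F = 0.05$), African-like ($F = 0.15$) and
East-Asian-like ($F = 0.12$) — enough to exercise every multi-ancestry
branch without modeling seven continental panels.

Each individual carries admixture proportions $q_{i\cdot}$ summing to 1;
the per-variant expected frequency is $\sum_k q_{ik} p_{vk}$. Two
haplotypes are drawn per individual with block LD: within a block of
`ld_block_size` variants, the latent uniform deciding each allele is
carried over from the previous variant with probability `ld_rho`, which
induces positive dosage correlation within blocks and exactly zero
between blocks, while leaving marginal frequencies untouched. This is
deliberately not a recombination-map model: clumping only needs
controllable $r^2$, and the block structure admits exact brute-force
oracles. Relatedness is injected by letting designated pairs share one
full haplotype (kinship $\approx 0.25$, first-degree-like).

### Phenotypes

Traits are built as
`baseline + covariate effects + scaled genetic value + group noise`.
Covariates are age (uniform 30–80 years), sex, BMI (normal, mean 28
kg/m², SD 5), and smoking status; default effect sizes are of plausible
clinical magnitude (e.g. 0.45 mmHg/year of age, 0.7 mmHg per kg/m² BMI
on SBP). Group residual SDs default to 17/19/18 mmHg for SBP, so the
African-like group has $(19/17)^2 \approx 1.25$ times the European-like
residual variance — the magnitude of between-group variance heterogeneity
reported for these traits. DBP uses 10/11.18/10.5 mmHg.

`heritability_prs` is defined as the fraction of *within-group* residual
(covariate-free) phenotypic variance attributable to the causal variants.
The within-group definition matters: allele-frequency divergence gives
the genetic value a between-group mean component, and the evaluation
models include group-specific intercepts that absorb exactly that
component. Scaling on total genetic variance would make the measured PVE
systematically undershoot the configured heritability; with the
within-group definition, PVE targets $100 \times h^2$ directly.

Antihypertensive medication: users (default probability 0.25 per group)
have their *observed* SBP/DBP lowered by 15/10 mmHg, representing
treatment. The standard medication adjustment — adding 15/10 mmHg back —
therefore recovers the underlying trait, making the adjustment testable
as parameter recovery rather than a bookkeeping identity.

### GWAS summary statistics

`simulate_gwas_sumstats()` has two modes. Regression mode runs the actual
covariate-adjusted single-SNP regressions on a cohort subset (vectorized
via Frisch–Waugh residualization; exact). Analytic mode emulates a large
external GWAS of size $n$: the covariate-adjusted marginal effect
$\beta_v$ of each variant is measured in the subset, and the reported
estimate is drawn as
$\hat\beta_v \sim N(\beta_v, \mathrm{se}_v)$ with
$\mathrm{se}_v = \sigma_e / \sqrt{2 n p_v (1-p_v)}$. Regression mode is
the ground truth; the analytic mode exists so that GWAS of hundreds of
thousands of individuals can be emulated in milliseconds, and the two are
cross-checked against each other in the test suite.

What the generator does *not* emulate: realistic human LD maps and
recombination, sequence-level error, the X chromosome, genotype
imputation artefacts, longitudinal measurement, and environmental or
gene-by-environment structure beyond the configured group variances.
Tests passing on this generator demonstrate correctness of the pipeline's
statistics under its assumptions, not the field performance of any PRS on
real cohorts.

## Harmonization

Variants are matched to the panel by chromosome and 1-based position on a
single genome build (no liftover), with the allele pair resolving
orientation: exact matches are kept, swapped pairs have the effect size
negated and the effect-allele frequency complemented, strand-ambiguous
pairs (A/T, C/G) are removed, and unmatched positions are dropped. No
frequency-based rescue of ambiguous variants is attempted, and
reverse-strand rescue is off: silently mis-oriented variants are worse
than dropped ones. QC keeps variants with MAF $\ge 0.01$ in both the GWAS
and the panel and panel missingness $< 0.01$. Reports partition the input
exactly (`input = retained + removed + unmatched`), which the tests
assert.

## PRS construction

Clumping is greedy by ascending p-value among variants passing the
threshold: select the best remaining variant, remove all unselected
variants on the same chromosome within `window_kb` whose squared dosage
correlation in the reference panel exceeds `r2_max`, repeat. Defaults
$r^2 = 0.1$ and 1000 kb, with inclusion thresholds
$\{5\times10^{-8}, 10^{-5}, 10^{-2}\}$. Ties on p-value are broken by
(chromosome, position), making output deterministic; clumped variants can
never later seed a clump; monomorphic panel variants are treated as
$r^2 = 0$ (they can tag nothing). The implementation is checked for exact
equality against an exhaustive re-scanning oracle on hundreds of random
instances.

Scoring is the additive dosage sum; missing dosages are imputed at twice
the panel allele frequency by default. Standardization centers and scales
to mean 0, variance 1 in a designated reference cohort; external cohorts
reuse the stored constants, so their means are informative (they shift by
$\sum_v w_v\, 2\Delta p_v / \mathrm{sd}_{ref}$ under allele-frequency
divergence, an identity the tests verify). Externally computed weight
tables (e.g. from Bayesian shrinkage methods) enter through the same
`weight_table` container and skip clumping.

## Multi-PRS combination

Combination weights are the coefficients of the component PRSs in a
single joint OLS of the training phenotype on covariates plus all
standardized components simultaneously (not marginal fits). Training can
be restricted to one background group (primary analysis) or use all
training individuals; both scopes are exposed and neither is privileged.
Negative weights pass through unmodified. In-sample, the weighted sum's
PVE dominates every component and the unweighted sum by OLS optimality —
asserted on every replicate in the acceptance suite; held-out dominance
holds on average.

Cross-dataset harmonization offers `none`, `scale` (match SDs), and
`scale_match` (monotone empirical-quantile mapping onto the target
distribution, linear interpolation between order statistics, ranks
preserved exactly).

## Association and PVE

The association model regresses the (medication-adjusted) trait on
group-specific intercepts, covariates and the PRS. Heterogeneous
residual variances by group are fit by feasible generalized least
squares: iterate weighted LS and per-group variance re-estimation until
the maximum relative change is below $10^{-8}$ (cap 50 iterations). With
a kinship matrix, a two-variance-component model
$y = X\beta + g + e$, $g \sim N(0, \sigma_g^2\, 2K)$, is fit by
profiling the likelihood over $h = \sigma_g^2/\sigma_{tot}^2$ on a grid
refined by golden-section search after rotating by the eigenvectors of
$2K$. The rotation diagonalizes the model only under a homogeneous
residual variance, so the kinship path uses homogeneous residuals;
heterogeneous variances are available in the non-kinship path. The PRS
test is a two-sided 1-df Wald test on the normal reference.

PVE follows

$$\mathrm{PVE} = \left(1 - \frac{\hat\sigma^2_{prs}}{\hat\sigma^2_{null}}\right)\times 100\%,$$

where $\hat\sigma^2_{prs}$ and $\hat\sigma^2_{null}$ are the residual
variances of the covariates+PRS and covariates-only models, both fit on
unrelated individuals (selected greedily from the sparse kinship graph at
threshold $2^{-4.5} \approx 4.4\%$; ties drop the lexicographically
larger id, making selection deterministic and order-invariant). Residual
variances are degrees-of-freedom adjusted. Negative PVE is reported
as-is. When group variances are heterogeneous, per-group FGLS variances
are pooled by degrees-of-freedom weighting before entering the ratio; a
homogeneous mode is the default and the two agree when groups coincide.
PVE is invariant to affine transforms of the PRS, and equals the
partial-$R^2$ route computed by residualizing covariates out — both
identities are asserted to $10^{-10}$.

Confidence intervals use the percentile bootstrap: individuals of the
fixed unrelated subset are resampled with replacement (the unrelated
selection is *not* redone per replicate — deterministic and cheap, and
the selection is not itself the statistic of interest), PVE recomputed,
and the 2.5/97.5 percentiles reported; 1000 replicates by default.
Empirical coverage is verified on simulated datasets (n = 800, 300
replicates each — the problem size chosen for the routine test runs).

Stratified evaluation repeats the fit and PVE within strata of age
($\le 40$, 40–60, $>60$; age exactly 40 falls in the first band, matching
the protocol's "$\le 40$" phrasing), sex, obesity (BMI $\ge 30$), and
medication use. Covariates constant within a stratum (sex inside a sex
stratum) are dropped from that stratum's model rather than producing a
singular design. Strata below 50 individuals are skipped with a warning.

AUC for binary outcomes is the Mann–Whitney statistic with midranks for
ties, checked against all-pairs enumeration and an independent ROC
implementation.

## Ancestry diagnostics

Ancestry-specific allele frequencies are estimated per variant by
box-constrained least squares under
$E[\mathrm{dosage}_i] = 2\sum_k q_{ik}\,p_k$ with $p_k \in [0,1]$ — a
documented simplification of local-ancestry-aware estimators, unbiased
when global proportions describe the genome-wide mixture. The
unconstrained normal-equation solution is used when it already satisfies
the box; otherwise L-BFGS-B with analytic gradient. Estimation precision
depends on the admixture design: a cohort of dominant-ancestry
individuals (the structure real multi-ethnic cohorts and this generator
produce) carries about three times the design information of a uniform
admixture cloud, and recovery tests use that structure.

A low-information ancestry (the Oceania-like case) can be dropped:
individuals with at most 5% of the dropped ancestry are renormalized to
sum to 1, the rest flagged excluded; the 5% cap is a configurable default
since "small fraction" is not standardized. Majority-ancestry groups use
an inclusive 80% cutoff.

The effect-versus-frequency profile bins clumped, associated variants
(p < 0.01) by deciles of each ancestry's estimated frequency and
summarizes $|\beta|$ per bin (median, IQR). Under a matched ancestry the
profile falls from both frequency extremes toward 0.5 (rare variants
carry larger effects — the "U" shape); under a mismatched ancestry the
frequencies are effectively shuffled and the profile flattens. The
binning into deciles is this package's choice; the qualitative contrast
is what the tests assert.

## The pipeline driver

`run_pipeline()` chains all stages under one validated configuration
(`pipeline_config()` or a YAML file): simulate → per-population GWAS →
harmonize → clump/threshold/score/standardize per GWAS and threshold →
train combination weights on a held-out split → unweighted and weighted
sums → prepare phenotypes and select unrelateds → stratified evaluation →
ancestry diagnostics. Every stochastic stage receives a seed derived from
the single run seed; a configuration without a seed is rejected before
anything runs. The run report (JSON) records seeds, per-stage record
counts, wall time and MD5 hashes of every output; re-running the same
configuration reproduces identical hashes.

```{r demo, eval = FALSE}
cfg <- demo_config(seed = 42L)
res <- run_pipeline(cfg, out_dir = tempfile("run"))
head(res$evaluation)
```

## Numerical choices and limitations

- Positions are 1-based throughout, matching VCF.
- FGLS convergence: relative variance change $< 10^{-8}$, at most 50
  iterations; non-convergence is an error, not a silent fallback.
- Bootstrap replicates with singular designs are redrawn (at most 10
  retries) and counted.
- The constrained frequency estimator reports the root-mean-squared
  residual per variant as a fit diagnostic.
- Routine test problem sizes: clumping oracles at ≤ 60 variants × 200
  panel individuals; PVE recovery at n = 10,000; coverage at 200 datasets
  × 300 bootstrap replicates; chosen to make sampling error small
  relative to the tolerances asserted.
- Out of scope by design: Bayesian shrinkage weight estimation (those
  weights are consumed, not produced), genome build liftover, indel and
  multi-allelic harmonization, local-ancestry inference, survival and
  incident-outcome analysis, and meta-analysis of summary statistics on
  different outcome scales.
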