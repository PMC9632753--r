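# slumr

Linear and non-linear Mendelian randomization (MR) for the causal
dose-response relationship between habitual sleep duration and
hyperuricemia, with a synthetic cohort generator so the entire analysis is
testable without access to individual-level biobank data.

The package is aimed at genetic epidemiologists and biostatisticians who
want the full analysis flow of a sex-stratified sleep/urate MR study as
reusable, tested components: the cross-sectional stage, instrument quality
control and risk-score construction, the linear MR estimator suite with
pleiotropy diagnostics, and residual-stratified non-linear MR with formal
non-linearity tests.

## What it computes

**Observational stage.** Hyperuricemia is serum urate ≥ 420 μmol/L (men) /
≥ 360 μmol/L (women). Sleep duration (integer hours/day) is grouped as
≤5, 6, 7 (reference), 8, ≥9. Category odds ratios come from logistic
regression (or the closed form *OR* = *ad*/*bc* with
SE(log *OR*) = √(1/a+1/b+1/c+1/d)), and the dose-response curve from a
four-knot restricted cubic spline in a logistic model, reported as OR
against 7 h/day.

**Genetic instruments.** QC thresholds INFO ≥ 0.9, MAF ≥ 0.01,
Hardy-Weinberg *p* ≥ 10⁻⁵, pairwise LD *r*² ≤ 0.1 (greedy pruning by
discovery *p*-value); the genetic risk score (GRS) is the unweighted count
of sleep-duration-increasing alleles; instrument strength is the partial
*R*² and *F* = (*n* − *k* − 1)·*R*²/(1 − *R*²).

**Linear MR.** Two-stage estimation (exposure on GRS, then outcome on the
fitted exposure, logistic for binary outcomes), plus the
summary-statistic estimators: Wald ratio with delta-method SE,
inverse-variance weighted (IVW) with Cochran's Q, MR-Egger (intercept =
average directional pleiotropy), weighted median, and MR-PRESSO
(simulation-based global heterogeneity test, per-SNP outlier detection,
outlier-corrected re-estimation). Binary-exposure (short/long sleep)
estimates are rescaled by ln 2 per doubling of genetic liability, with
Bonferroni families of 3 and 6.

**Non-linear MR.** The sample is stratified on the IV-free exposure
(residual of sleep duration on the GRS); in each stratum the localized
average causal effect (LACE) is the ratio of the GRS-outcome to the
GRS-exposure coefficient; the piecewise linear causal curve is
continuity-constrained and anchored at 7 h/day; non-linearity is tested by
Cochran's Q over the LACE set and by an inverse-variance meta-regression
of LACE on stratum mean exposure (the quadratic test).

**Synthetic cohorts.** `sim_config()`/`simulate_cohort()` generate
genotypes in Hardy-Weinberg equilibrium, an exposure whose genetic
component explains a configurable variance fraction, a hidden confounder,
optional horizontal pleiotropy, and a binary outcome whose prevalence is
calibrated by bisection to 0.13 ± 0.005 under a configurable causal shape
(null, linear, U, J) — with all hidden truths returned for validation.

## Worked example

```r
library(slumr)

cfg <- sim_config(n_samples = 20000, n_snps = 77,
                  causal_shape = "quadratic_u",
                  causal_params = list(curvature = 0.15),  # U-shape, vertex 7 h
                  seed = 2024)
cohort <- simulate_cohort(cfg)

qc  <- qc_filter(cohort$genotypes)
grs <- build_grs(cohort$genotypes, snps = attr(qc, "retained"))

mr_two_stage(grs, cohort$phenotypes$exposure, cohort$phenotypes$hyperuricemia)
#> MR estimate [two_stage], scale: per_hour
#>   beta = 0.3622 (SE 0.1988), 95% CI [-0.0274, 0.7517], p = 0.0684
#>   OR = 1.436 (95% CI 0.973-2.121)
#>   instruments: 77 SNPs

nonlinear_mr(grs, cohort$phenotypes$exposure, cohort$phenotypes$hyperuricemia,
             k = 3, min_stratum = 200, seed = 1)
#> Non-linear MR over 3 strata (reference 7 h/day)
#>   stratum 1 (n = 6666, mean 5.97 h): LACE -1.0522 (SE 0.3566)
#>   stratum 2 (n = 6667, mean 7.18 h): LACE 1.1460 (SE 0.3750)
#>   stratum 3 (n = 6667, mean 8.37 h): LACE 1.0082 (SE 0.3340)
#>   Cochran Q = 23.835 (p = 6.67e-06); quadratic test p = 3.55e-05
```

The linear two-stage estimate is near-null — averaging over a U-shape
hides it — while the stratum LACEs change sign from the short-sleep to the
long-sleep stratum and both non-linearity tests reject decisively: the
generated U-shaped causal effect is recovered by the non-linear stage and
missed by the linear one, which is the methodological point of the
analysis.

A full orchestrated run (QC → GRS → observational → linear → non-linear →
binary-exposure, overall and by sex) is one call:

```r
report <- run_pipeline(run_config(simulation = cfg, seed = 1),
                       out_dir = "run1")
```

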