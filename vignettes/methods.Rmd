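---
title: "Linear and non-linear Mendelian randomization for sleep duration and hyperuricemia: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linear and non-linear Mendelian randomization for sleep duration and hyperuricemia: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slumr)
```

## The scientific problem

Observational studies repeatedly find that people who sleep much less or
much more than about seven hours a day have higher rates of hyperuricemia
(serum urate at or above 420 μmol/L in men, 360 μmol/L in women). Because
sleep behaviour is entangled with deprivation, lifestyle, adiposity and
metabolic disease, the observational dose-response curve cannot be read
causally. Mendelian randomization (MR) addresses this by using common
genetic variants associated with sleep duration — allocated at conception
and therefore independent of later-life confounders — as instrumental
variables. Standard MR, however, assumes a *linear* exposure-outcome
relationship, which is exactly what a U-shaped association violates, so the
package also implements a stratified, non-linear MR procedure.

`slumr` reimplements this complete analysis flow as reusable, tested
components: the cross-sectional stage, instrument quality control and
risk-score construction, linear MR with pleiotropy diagnostics, non-linear
MR with formal non-linearity tests, and a synthetic cohort generator so
that every stage can be exercised and validated without access to
individual-level biobank data.

## The synthetic cohort generator

`sim_config()` / `simulate_cohort()` generate data with the structure the
analysis assumes:

* **Genotypes.** Each instrument SNP is drawn as two independent allele
  draws (dosage 0/1/2) at a frequency sampled from `maf_range`, so
  Hardy-Weinberg equilibrium holds by construction and SNPs are mutually
  independent. Linkage disequilibrium is deliberately *not* simulated; the
  LD-pruning logic is tested on explicitly constructed correlated columns
  instead.
* **Exposure.** Sleep duration is continuous,
  `X = mean + genetic score + confounder + noise`, with mean 7.16 h and SD
  1.1 h (typical of adult self-report), and the residual scaled so the
  genetic component explains exactly `r2_grs` of the exposure variance.
  The integer self-report used by the observational stage is the rounded
  value.
* **Instrument strength.** The generator is calibrated through variance
  explained rather than per-allele effects. The default `r2_grs = 0.01`
  keeps the first-stage F-statistic in the hundreds at the package's
  default working scale of 20 000–50 000 samples and comfortably above the
  conventional weak-instrument bar of F > 10 even in sex-stratified
  subsets. At biobank scale (n of several hundred thousand) a value of
  about 8×10⁻⁴ reproduces first-stage F-statistics of the order of 300,
  the magnitude reported for well-powered sleep instruments; variance
  explained by sleep scores is not itself a published quantity, so these
  are calibration choices, not reproduced values.
* **Outcome.** Binary hyperuricemia follows
  `logit P(Y=1) = β₀ + f(X) + λU + Σ δⱼGⱼ`, where `f` is the configured
  causal shape (`null`, `linear`, `quadratic_u` with vertex at 7 h,
  or `piecewise_j`), `U` is a single standard-normal hidden confounder,
  and the `δⱼ` give a configurable fraction of SNPs direct (pleiotropic)
  outcome effects, balanced or directional. The intercept `β₀` is solved
  by bisection so the marginal prevalence matches `baseline_prevalence`
  (default 0.13) to within 0.005; unattainable prevalences raise an error
  naming the offending parameters. A urate value consistent with the
  simulated case status is drawn from the sex-specific truncated normal
  tails so that classification and outcome always agree.
* **Binary exposures.** Short- and long-sleep analyses use a
  liability-threshold exposure: the indicator of a latent liability
  (loaded on the same genetic score) exceeding its
  `1 − exposure_prevalence` quantile. Defaults of 24% (short) and 8%
  (long) mirror the population shares of short and long sleepers.
* **Sex-specific shapes.** An optional female-specific causal shape
  supports the end-to-end sex-contrast checks (for example a female-only
  U-shape over a male null).
* **Seeding.** One master seed; every stage draws from a deterministic
  child stream, so identical configurations are bitwise reproducible.

What the generator does *not* emulate: linkage disequilibrium, assortative
mating, population stratification, genotyping/imputation error (INFO
scores are metadata pass-throughs), item non-response patterns, or the
covariate correlation structure of a real cohort. Passing tests therefore
demonstrate the correctness and calibration of the *statistical machinery*
under the stated generative model, not robustness to all features of real
biobank data.

## Observational stage

`classify_hyperuricemia()` applies the sex-specific urate thresholds with
boundary values counted as cases. `categorize_sleep()` maps integer hours
into the five conventional groups (≤5, 6, 7, 8, ≥9 h/day) with 7 h as the
reference. `contingency_or()` computes the closed-form odds ratio with the
Wald interval from `SE(log OR) = √(1/a+1/b+1/c+1/d)`; zero cells raise an
error rather than applying a hidden continuity correction.
`fit_category_or()` fits the maximum-likelihood logistic model (converged
to `epsilon = 1e-12` so that the unadjusted fit reproduces the closed-form
contingency odds ratio to many significant digits) and reports Wald
intervals throughout; profile-likelihood intervals are not implemented
because the normal-theory intervals are what the published category tables
reconstruct to.

The dose-response curve uses a restricted cubic spline with four knots,
written in the classical truncated-power form (linear beyond the outer
knots, `k − 1` non-intercept columns for `k` knots). Knot placement
follows the standard quantile convention (5th, 35th, 65th, 95th
percentiles) and is overridable. Because integer-valued self-report makes
quantiles collide, coincident knots are moved to the nearest distinct
observed values (with a warning) by an index-clamping scheme that always
succeeds when there are at least as many distinct values as knots. The
curve is reported as the odds ratio against the reference exposure — the
linear-predictor contrast `B(x) − B(7)` — so OR(7) is exactly 1 with a
zero-width interval, and pointwise bands come from the delta method on
that contrast.

## Instrument QC and the risk score

`qc_filter()` applies the conventional thresholds (INFO ≥ 0.9, MAF ≥ 0.01,
Hardy-Weinberg p ≥ 1×10⁻⁵) and then LD-prunes survivors greedily in
ascending discovery p-value order so that every retained pair has
r² ≤ 0.1; every per-SNP decision is recorded with named reasons, and an
empty survivor set is a valid logged outcome. The Hardy-Weinberg test is
the 1-df chi-square goodness-of-fit test; an exact test is not implemented
because at the sample sizes involved the asymptotic test is adequate, and
imputed (non-integer) dosages are rounded to best-guess genotypes with a
warning. The published post-QC instrument counts (77/26/7) depend on
genotypes this package cannot access, so the QC *logic* is verified on
constructed fixtures instead.

`build_grs()` forms the unweighted count of exposure-increasing alleles,
re-orienting dosages (`d → 2 − d`) where the increasing allele is the
non-effect allele; the score is invariant to how the input happens to be
oriented. `instrument_strength()` reports the partial R² of the score
given covariates and the exact single-degree-of-freedom ANOVA F,
`F = (n − k − 1) r² / (1 − r²)`.

## Linear MR

`mr_two_stage()` implements the two-stage method: least squares of
exposure on score (plus covariates), then logistic regression of the
outcome on the fitted exposure (plus the same covariates). Two caveats are
deliberate properties of the method rather than bugs, and are surfaced in
documentation: the default second-stage SE ignores first-stage
uncertainty (an optional seedable nonparametric bootstrap propagates both
stages; it is off by default since the analysis being reproduced reports
single normal-theory intervals), and a logistic second stage is a
non-collapsible approximation (the "forbidden regression" caveat).
First-stage F is always computed and logged; F < 10 attaches a prominent
weak-instrument warning.

The summary-statistic suite operates on per-SNP association tables
(`compute_summary_stats()` bridges the individual-level simulation to
these estimators):

* **Wald ratio** — `β = β_out/β_exp` with the full second-order
  delta-method SE.
* **IVW** — fixed-effect weighted regression through the origin with
  weights `1/se_out²`; Cochran's Q on `n − 1` df measures heterogeneity.
* **MR-Egger** — the same regression with a free intercept after
  orienting every SNP so its exposure effect is non-negative (required
  for the intercept to measure average directional pleiotropy); residual
  dispersion is floored at 1.
* **Weighted median** — the 50% point of the inverse-variance-weighted
  cumulative distribution of sorted per-SNP ratios, interpolated between
  bracketing ratios, with first-order ratio weights and a seedable
  parametric bootstrap SE (default 1000 draws).
* **MR-PRESSO** — the observed residual sum of squares from leave-one-out
  IVW predictions is compared against parametric simulations under the
  no-pleiotropy model; the global and per-SNP p-values use the
  `(1 + k)/(1 + n_sim)` tail estimator so they can never be exactly zero,
  and per-SNP outlier tests are Bonferroni-corrected. A consequence of the
  tail estimator is a resolution floor: with `B` simulations the smallest
  achievable adjusted p is `n_snps/(1 + B)`, so `mr_presso()` warns when
  `n_sim` is too small for any outlier to be flaggable at the requested
  level. The corrected estimate is IVW after removing flagged outliers;
  if every SNP is flagged there is no estimate and an error is raised.

Binary-exposure (short/long sleep) estimates are rescaled by `ln 2` via
`rescale_binary_exposure()` to read per doubling of genetic liability;
the z-score and p-value are unchanged and an idempotence guard prevents
double rescaling. `bonferroni_flag()` applies the strict `p < α/m` rule
(families of 3 for the three populations and 6 for the short/long ×
population grid).

## Non-linear MR

The residual-stratification method: `iv_free_exposure()` removes the
genetically predicted part of the exposure, `stratify_residuals()` cuts
the residuals into `k` near-equal strata by rank (ties broken by stable
input order; default `k = 3`, minimum stratum size 500 at the default
working scale), and `lace_per_stratum()` estimates the localized average
causal effect in each stratum as the ratio of the stratum-specific
score-outcome coefficient to the score-exposure coefficient, with the
Wald-ratio SE.

Two design points deserve emphasis:

* **The LACE denominator** defaults to the *full-sample* score-exposure
  coefficient. Within-stratum fits on residual-defined strata attenuate
  the denominator (the stratification consumes part of the non-genetic
  exposure variation), and the residual-stratification literature uses
  the full-sample association; a `denominator = "stratum"` switch exposes
  the alternative, and a property test checks the two are statistically
  compatible on simulated data.
* **Stratifying on residuals, not raw exposure**, avoids selecting on the
  instrument; the doubly-ranked alternative is not implemented because
  the procedure being reproduced describes the residual method only.

`piecewise_curve()` integrates the LACE slopes into the causal curve:
segment `k` has slope `LACE_k` between the `(k−1)/K` and `k/K` quantiles
of the observed exposure, each segment begins where the previous one
finished (continuity is exact by construction, not approximate), and the
curve is anchored at 0 at the reference exposure of 7 h. Pointwise bands
are percentile intervals over independent normal draws of the LACE vector
(default 2000 draws; the band-construction method for the original curve
is unstated, so a parametric draw was chosen as the simplest seedable
scheme); the band has exactly zero width at the reference.

Non-linearity is tested twice: `cochran_q_test()` (inverse-variance
heterogeneity of the LACE set, χ² on `K − 1` df) and `quadratic_test()`
(inverse-variance meta-regression of LACE on stratum mean exposure; a
nonzero slope of the *local* effect in exposure is exactly a quadratic
term in the *cumulative* curve, and with `K = 3` the slope is referred to
the normal distribution).

## Orchestration

`run_config()` (or `run_config_from_yaml()`) plus `run_pipeline()` tie the
stages together: simulate → QC → score → observational → linear MR →
non-linear MR → binary-exposure MR, with sex-specific runs as filtered
repeats, exclusion-flow counts that sum exactly, every stage warning
surfaced in the report, and all artifacts written as TSVs plus one JSON
report. The package is driven from R; the configuration file plus
`run_pipeline()` is the reproducible entry point, and all randomness
descends from the single run seed.

## Numerical choices and degenerate inputs

* Logistic fits converge to `epsilon = 1e-12` where closed-form
  equivalences are asserted; elsewhere the `glm.fit` defaults apply.
* Bisection for the prevalence intercept runs on `[−40, 40]` to tolerance
  1e-6 and errors (naming the parameters) when the link saturates.
* Zero cells in 2×2 tables, constant exposures, constant scores,
  monomorphic SNPs, separation in logistic fits, zero `β_exp` in Wald
  ratios, zero LACE SEs, and all-identical residuals are rejected with
  specific errors rather than silently patched; monomorphic SNPs in
  summary-statistic computation are excluded with a warning.
* Ties in stratification are broken by stable input order, making the
  assignment deterministic.

## Problem sizes used in the validation suite

The test suite validates operating characteristics by simulation at sizes
chosen to give informative Monte-Carlo error while remaining desk-scale:
type-I error of the non-linearity tests at n = 5 000 over 500 replicates;
quadratic-test power at n = 100 000 over 200 replicates; CI coverage of
the two-stage and IVW estimators at n = 50 000 over 100 replicates;
MR-PRESSO spike-in detection over 60 replicates with 600 simulations
each. These are the package's validation design points, and the same
quantities are recomputed by `scripts/acceptance.R`.

## Known limitations

* Individual-level results from the original cohort (its MR odds ratios,
  Q and quadratic p-values) depend on access-controlled data and are
  treated as qualitative anchors only; what the package validates is the
  machinery, on synthetic cohorts with known truths.
* The quadratic test's power at a curvature of 0.05 log-odds/h² is
  modest at realistic instrument strength: at n = 100 000 with the score
  explaining 1% of exposure variance, the stratum LACE SEs (~0.15) give a
  meta-regression slope SE near 0.09 against a true slope of 0.1, i.e.
  power around 20%. Detecting curvature of this size with high
  probability would require either several-fold larger samples or an
  implausibly strong instrument; this is a property of the design, which
  the validation suite measures and reports honestly rather than
  engineering around.
* The two-stage estimator's default SE understates uncertainty when the
  first stage is imprecise (use the bootstrap option); the logistic
  second stage estimates a conditional, non-collapsible odds ratio.
* No LD-aware instrument selection, no multivariable MR, no
  contamination-mixture or mode-based estimators, no fractional
  polynomial non-linear MR, and no survey weighting or imputation.
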