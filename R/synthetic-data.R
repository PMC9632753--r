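#' Simulation configuration for a synthetic sleep-duration cohort
#'
#' Bundles the generative parameters for [simulate_cohort()]. The defaults
#' emulate the structure of a large population cohort in which habitual
#' sleep duration (hours/day, mean about 7.2, SD about 1.1) is instrumented
#' by a few dozen independent common variants that jointly explain a small
#' fraction of the exposure variance, and hyperuricemia is a binary outcome
#' with about 13% marginal prevalence.
#'
#' The genetic signal is calibrated through `r2_grs`, the fraction of
#' exposure variance explained by the allele score, rather than through
#' per-allele effect sizes: at biobank scale (n of several hundred thousand)
#' an `r2_grs` of 8e-4 yields a first-stage F-statistic of about 300, the
#' order of magnitude reported for well-powered sleep instruments; at the
#' package's default working scale (tens of thousands of samples) the
#' default of 0.01 keeps the instrument comfortably above the F > 10
#' weak-instrument bar.
#'
#' @param n_samples Number of individuals.
#' @param n_snps Number of independent instrument SNPs.
#' @param maf_range Length-2 numeric, the range that minor allele
#'   frequencies are drawn from; must lie within (0, 0.5].
#' @param r2_grs Target fraction of exposure variance explained by the
#'   combined genetic score, in (0, 1).
#' @param causal_shape One of `"null"`, `"linear"`, `"quadratic_u"`,
#'   `"piecewise_j"`: the true exposure--outcome dose-response shape on the
#'   log-odds scale (or outcome-unit scale for a continuous outcome).
#' @param causal_params Named list of shape coefficients:
#'   `slope` (per hour) for `"linear"`; `curvature` (per hour squared) and
#'   `vertex` (hours, default 7) for `"quadratic_u"`; `slope_left`,
#'   `slope_right` and `vertex` for `"piecewise_j"`.
#' @param confounder_effect_exposure Hours of exposure per SD of the hidden
#'   confounder.
#' @param confounder_effect_outcome Log-odds (or outcome units) per SD of
#'   the hidden confounder.
#' @param pleiotropy_fraction Fraction of SNPs given direct outcome effects.
#' @param pleiotropy_scale Log-odds per allele for pleiotropic SNPs.
#' @param pleiotropy_balanced If `TRUE` pleiotropic effects have random
#'   signs (balanced pleiotropy); if `FALSE` all are positive (directional).
#' @param baseline_prevalence Target marginal outcome prevalence for the
#'   binary family, in (0, 1).
#' @param outcome_family `"binary"` (hyperuricemia) or `"continuous"`
#'   (serum urate in micromol/L).
#' @param exposure_family `"continuous"` (hours/day) or
#'   `"binary_liability"`: a 0/1 exposure indicator thresholding a latent
#'   liability loaded on the allele score, as used for short/long-sleep
#'   analyses.
#' @param exposure_mean,exposure_sd Mean and SD of the continuous exposure
#'   (hours/day).
#' @param exposure_prevalence Prevalence of the binary exposure indicator
#'   when `exposure_family = "binary_liability"`.
#' @param urate_mean,urate_sd Mean and SD of serum urate (micromol/L) for
#'   the continuous outcome family.
#' @param sex_male_fraction Fraction of males in the cohort.
#' @param causal_shape_female,causal_params_female Optional sex-specific
#'   override of the causal shape for females (males keep `causal_shape`);
#'   `NULL` means no sex difference.
#' @param n_pcs Number of standard-normal "principal component" noise
#'   covariates to attach to the phenotype table.
#' @param seed Master seed; all randomness in [simulate_cohort()] derives
#'   from it through deterministic child streams.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [simulate_cohort()], [simulate_genotypes()]
#' @export
sim_config <- function(n_samples = 20000,
                       n_snps = 77,
                       maf_range = c(0.05, 0.45),
                       r2_grs = 0.01,
                       causal_shape = c("null", "linear", "quadratic_u",
                                        "piecewise_j"),
                       causal_params = list(),
                       confounder_effect_exposure = 0,
                       confounder_effect_outcome = 0,
                       pleiotropy_fraction = 0,
                       pleiotropy_scale = 0,
                       pleiotropy_balanced = TRUE,
                       baseline_prevalence = 0.13,
                       outcome_family = c("binary", "continuous"),
                       exposure_family = c("continuous", "binary_liability"),
                       exposure_mean = 7.16,
                       exposure_sd = 1.1,
                       exposure_prevalence = 0.24,
                       urate_mean = 310,
                       urate_sd = 80,
                       sex_male_fraction = 0.46,
                       causal_shape_female = NULL,
                       causal_params_female = NULL,
                       n_pcs = 0,
                       seed = 1L) {
  causal_shape <- match.arg(causal_shape)
  outcome_family <- match.arg(outcome_family)
  exposure_family <- match.arg(exposure_family)
  if (!is_count(n_samples)) stop2("`n_samples` must be a positive integer")
  if (!is_count(n_snps)) stop2("`n_snps` must be a positive integer")
  if (length(maf_range) != 2L || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    stop2("`maf_range` must be an increasing pair within (0, 0.5]")
  check_fraction(r2_grs, "r2_grs", open = TRUE)
  check_fraction(pleiotropy_fraction, "pleiotropy_fraction")
  if (outcome_family == "binary")
    check_fraction(baseline_prevalence, "baseline_prevalence", open = TRUE)
  check_fraction(exposure_prevalence, "exposure_prevalence", open = TRUE)
  check_fraction(sex_male_fraction, "sex_male_fraction")
  if (exposure_sd <= 0) stop2("`exposure_sd` must be positive")
  causal_params <- default_causal_params(causal_shape, causal_params)
  if (!is.null(causal_shape_female)) {
    causal_shape_female <- match.arg(causal_shape_female,
                                     c("null", "linear", "quadratic_u",
                                       "piecewise_j"))
    causal_params_female <- default_causal_params(
      causal_shape_female, causal_params_female %||% list())
  }
  cfg <- list(n_samples = as.integer(n_samples), n_snps = as.integer(n_snps),
              maf_range = as.numeric(maf_range), r2_grs = r2_grs,
              causal_shape = causal_shape, causal_params = causal_params,
              confounder_effect_exposure = confounder_effect_exposure,
              confounder_effect_outcome = confounder_effect_outcome,
              pleiotropy_fraction = pleiotropy_fraction,
              pleiotropy_scale = pleiotropy_scale,
              pleiotropy_balanced = isTRUE(pleiotropy_balanced),
              baseline_prevalence = baseline_prevalence,
              outcome_family = outcome_family,
              exposure_family = exposure_family,
              exposure_mean = exposure_mean, exposure_sd = exposure_sd,
              exposure_prevalence = exposure_prevalence,
              urate_mean = urate_mean, urate_sd = urate_sd,
              sex_male_fraction = sex_male_fraction,
              causal_shape_female = causal_shape_female,
              causal_params_female = causal_params_female,
              n_pcs = as.integer(n_pcs), seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

default_causal_params <- function(shape, params) {
  defaults <- switch(shape,
    null = list(),
    linear = list(slope = 0.1),
    quadratic_u = list(curvature = 0.05, vertex = 7),
    piecewise_j = list(slope_left = -0.02, slope_right = 0.15, vertex = 7))
  utils::modifyList(defaults, params)
}

# Evaluate the configured causal shape f(x) on the linear-predictor scale.
causal_f <- function(x, shape, params) {
  switch(shape,
    null = rep(0, length(x)),
    linear = params$slope * x,
    quadratic_u = params$curvature * (x - params$vertex)^2,
    piecewise_j = params$slope_left * pmin(x - params$vertex, 0) +
      params$slope_right * pmax(x - params$vertex, 0))
}

#' Simulate a matrix of biallelic genotype dosages
#'
#' Draws each SNP column as two independent allele draws with the given
#' effect-allele frequency, so genotypes are in Hardy-Weinberg equilibrium
#' by construction and dosages take values in {0, 1, 2}.
#'
#' @param n Number of individuals (rows).
#' @param mafs Numeric vector of effect-allele frequencies, each in
#'   (0, 0.5].
#' @param seed Integer seed.
#' @param info Optional imputation-quality (INFO) scores per SNP; default 1
#'   (directly genotyped). Metadata pass-through only.
#' @param gwas_p Optional discovery GWAS p-values per SNP; defaults to
#'   values drawn below genome-wide significance. Used to prioritise SNPs
#'   during LD pruning.
#' @param snp_ids Optional SNP identifiers; defaults to `snp_001`, ...
#'
#' @return A `genotype_matrix`: a list with `dosages` (n x p integer-valued
#'   matrix with SNP ids as column names) and `meta` (one row per SNP:
#'   `snp_id`, `effect_allele`, `other_allele`, `eaf`, `info`, `gwas_p`).
#' @export
simulate_genotypes <- function(n, mafs, seed = 1L, info = NULL,
                               gwas_p = NULL, snp_ids = NULL) {
  if (!is_count(n)) stop2("`n` must be a positive integer")
  bad <- which(!(mafs > 0 & mafs <= 0.5))
  if (length(bad))
    stop2("allele frequency out of (0, 0.5] for SNP %d (maf = %g)",
          bad[1], mafs[bad[1]])
  p <- length(mafs)
  if (is.null(snp_ids)) snp_ids <- sprintf("snp_%03d", seq_len(p))
  set.seed(seed)
  dos <- matrix(stats::rbinom(n * p, 2L, rep(mafs, each = n)), nrow = n,
                dimnames = list(NULL, snp_ids))
  alleles <- c("A", "C", "G", "T")
  ea <- sample(alleles, p, replace = TRUE)
  oa <- vapply(ea, function(a) sample(setdiff(alleles, a), 1L), character(1))
  if (is.null(info)) info <- rep(1, p)
  if (is.null(gwas_p)) gwas_p <- 10^stats::runif(p, -30, log10(5e-8))
  meta <- data.frame(snp_id = snp_ids, effect_allele = ea, other_allele = oa,
                     eaf = mafs, info = info, gwas_p = gwas_p,
                     stringsAsFactors = FALSE)
  structure(list(dosages = dos, meta = meta), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs\n",
              nrow(x$dosages), ncol(x$dosages)))
  cat(sprintf("  EAF range %.3f-%.3f; INFO range %.2f-%.2f\n",
              min(x$meta$eaf), max(x$meta$eaf),
              min(x$meta$info), max(x$meta$info)))
  invisible(x)
}

#' Simulate an individual-level cohort with a known causal structure
#'
#' Generates genotypes, a continuous (or liability-thresholded binary)
#' exposure, a hidden confounder, and a binary or continuous outcome under
#' a configurable causal dose-response shape, with optional horizontal
#' pleiotropy. The exposure model is
#' `X = mean + sum(gamma_j G_j) + kappa U + eps` with `U` standard normal
#' and the residual scaled so the genetic component explains `r2_grs` of
#' the exposure variance; the binary outcome follows
#' `logit P(Y = 1) = beta0 + f(X) + lambda U + sum(delta_j G_j)` with the
#' intercept solved by bisection so the marginal prevalence matches
#' `baseline_prevalence` to within 0.005.
#'
#' All hidden truths (confounder values, per-SNP exposure effects, the
#' pleiotropic effects, the solved intercept and the shape function) are
#' returned so tests can assert recovery.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `mr_cohort`: a list with `genotypes`
#'   (a `genotype_matrix`), `phenotypes` (data.frame: `exposure`,
#'   `sleep_hours` (integer self-report), `urate`, `hyperuricemia` or
#'   continuous outcome, `sex`, covariates) and `truth` (generative
#'   quantities).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  n <- cfg$n_samples
  p <- cfg$n_snps

  set.seed(child_seed(cfg$seed, 1L))
  mafs <- stats::runif(p, cfg$maf_range[1], cfg$maf_range[2])
  geno <- simulate_genotypes(n, mafs, seed = child_seed(cfg$seed, 2L))
  G <- geno$dosages

  set.seed(child_seed(cfg$seed, 3L))
  # Per-SNP exposure effects: equal raw loadings rescaled so the genetic
  # component hits the target variance fraction.
  gamma_raw <- rep(1, p)
  S <- as.vector(G %*% gamma_raw)
  var_x <- cfg$exposure_sd^2
  s <- sqrt(cfg$r2_grs * var_x / stats::var(S))
  gamma <- gamma_raw * s
  genetic <- s * (S - mean(S))

  kappa <- cfg$confounder_effect_exposure
  var_eps <- var_x - cfg$r2_grs * var_x - kappa^2
  if (var_eps <= 0)
    stop2(paste("exposure variance budget exhausted: r2_grs = %g and",
                "confounder_effect_exposure = %g exceed exposure_sd^2 = %g"),
          cfg$r2_grs, kappa, var_x)
  U <- stats::rnorm(n)
  eps <- stats::rnorm(n, sd = sqrt(var_eps))
  X_cont <- cfg$exposure_mean + genetic + kappa * U + eps

  if (cfg$exposure_family == "binary_liability") {
    # Liability-threshold exposure: indicator of latent liability above the
    # (1 - prevalence) quantile; liability loaded on the same score.
    liability <- genetic + kappa * U + eps
    thr <- stats::quantile(liability, 1 - cfg$exposure_prevalence)
    X <- as.numeric(liability > thr)
  } else {
    X <- X_cont
  }

  set.seed(child_seed(cfg$seed, 4L))
  sex <- factor(ifelse(stats::runif(n) < cfg$sex_male_fraction,
                       "male", "female"), levels = c("male", "female"))

  f_val <- causal_f(X, cfg$causal_shape, cfg$causal_params)
  if (!is.null(cfg$causal_shape_female)) {
    fem <- sex == "female"
    f_val[fem] <- causal_f(X[fem], cfg$causal_shape_female,
                           cfg$causal_params_female)
  }

  n_pleio <- round(cfg$pleiotropy_fraction * p)
  delta <- numeric(p)
  if (n_pleio > 0) {
    idx <- seq_len(n_pleio)
    sgn <- if (cfg$pleiotropy_balanced)
      sample(c(-1, 1), n_pleio, replace = TRUE) else rep(1, n_pleio)
    delta[idx] <- sgn * cfg$pleiotropy_scale
  }
  eta <- f_val + cfg$confounder_effect_outcome * U +
    as.vector(G %*% delta)

  set.seed(child_seed(cfg$seed, 5L))
  ph <- data.frame(exposure = X,
                   sleep_hours = pmin(pmax(round(X_cont), 0L), 23L),
                   sex = sex)
  truth <- list(gamma = gamma, confounder = U, delta = delta,
                f = f_val, mafs = mafs,
                shape = cfg$causal_shape, params = cfg$causal_params)

  if (cfg$outcome_family == "binary") {
    beta0 <- solve_prevalence_intercept(eta, cfg$baseline_prevalence)
    pr <- stats::plogis(beta0 + eta)
    y <- stats::rbinom(n, 1L, pr)
    ph$hyperuricemia <- y
    ph$urate <- simulate_urate_given_status(y, sex, cfg)
    truth$beta0 <- beta0
    truth$prob <- pr
  } else {
    # Continuous family: eta is in micromol/L; residual scaled so the
    # marginal SD approximates urate_sd.
    resid_var <- max(cfg$urate_sd^2 - stats::var(eta), cfg$urate_sd^2 * 0.05)
    ph$urate <- cfg$urate_mean + eta - mean(eta) +
      stats::rnorm(n, sd = sqrt(resid_var))
    ph$hyperuricemia <- classify_hyperuricemia(ph$urate, sex)
  }

  set.seed(child_seed(cfg$seed, 6L))
  ph$age <- stats::rnorm(n, 56.9, 8)
  ph$centre <- factor(sample(paste0("centre_", 1:4), n, replace = TRUE))
  ph$array <- factor(sample(c("axiom", "bileve"), n, replace = TRUE,
                            prob = c(0.9, 0.1)))
  if (cfg$n_pcs > 0) {
    pcs <- matrix(stats::rnorm(n * cfg$n_pcs), n,
                  dimnames = list(NULL, paste0("pc", seq_len(cfg$n_pcs))))
    ph <- cbind(ph, pcs)
  }
  ph$confounder_truth <- U

  structure(list(genotypes = geno, phenotypes = ph, truth = truth,
                 config = cfg), class = "mr_cohort")
}

#' @export
print.mr_cohort <- function(x, ...) {
  cat(sprintf("mr_cohort: %d individuals, %d SNPs, shape '%s' (%s outcome)\n",
              nrow(x$phenotypes), ncol(x$genotypes$dosages),
              x$config$causal_shape, x$config$outcome_family))
  if (!is.null(x$phenotypes$hyperuricemia))
    cat(sprintf("  outcome prevalence: %.3f\n",
                mean(x$phenotypes$hyperuricemia)))
  invisible(x)
}

# Solve the logistic intercept so mean(plogis(b0 + eta)) hits the target
# prevalence; bisection on a monotone function.
solve_prevalence_intercept <- function(eta, prevalence, tol = 1e-6) {
  g <- function(b0) mean(stats::plogis(b0 + eta)) - prevalence
  lo <- -40; hi <- 40
  if (g(lo) > 0 || g(hi) < 0)
    stop2(paste("target prevalence %.3f unattainable: the linear predictor",
                "saturates the logistic link (range of eta: [%.2f, %.2f])"),
          prevalence, min(eta), max(eta))
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# Urate values consistent with a simulated hyperuricemia status: cases drawn
# above the sex-specific threshold, non-cases below (truncated normals).
simulate_urate_given_status <- function(y, sex, cfg) {
  thr <- ifelse(sex == "male", 420, 360)
  n <- length(y)
  u <- numeric(n)
  # Inverse-CDF sampling within the allowed tail of N(urate_mean, urate_sd).
  pthr <- stats::pnorm(thr, cfg$urate_mean, cfg$urate_sd)
  r <- stats::runif(n)
  q <- ifelse(y == 1L, pthr + r * (1 - pthr) * 0.999, r * pthr)
  u <- stats::qnorm(q, cfg$urate_mean, cfg$urate_sd)
  pmax(u, 0)
}

#' Per-SNP association summary statistics from individual-level data
#'
#' Computes, for every SNP, the slope and standard error from a simple
#' (unadjusted) linear regression of the exposure on dosage, and from a
#' logistic (binary outcome) or linear (continuous outcome) regression of
#' the outcome on dosage. This bridges the individual-level simulation to
#' the summary-statistic estimators ([mr_ivw()], [mr_egger()],
#' [mr_weighted_median()], [mr_presso()]).
#'
#' @param g A `genotype_matrix`.
#' @param ph Phenotype data.frame aligned row-for-row with `g`; must
#'   contain `exposure` and the outcome column.
#' @param outcome_family `"binary"` or `"continuous"`.
#' @param outcome_col Outcome column name; defaults to `"hyperuricemia"`
#'   for binary and `"urate"` for continuous.
#' @return A `snp_summary` data.frame: `snp_id`, `beta_exp`, `se_exp`,
#'   `beta_out`, `se_out`, `eaf`. Monomorphic SNPs are excluded with a
#'   warning.
#' @export
compute_summary_stats <- function(g, ph,
                                  outcome_family = c("binary", "continuous"),
                                  outcome_col = NULL) {
  outcome_family <- match.arg(outcome_family)
  stopifnot(inherits(g, "genotype_matrix"))
  G <- g$dosages
  n <- nrow(G)
  if (nrow(ph) != n) stop2("phenotypes (%d rows) not aligned with genotypes (%d)",
                           nrow(ph), n)
  if (n < 30) stop2("need at least 30 samples for summary statistics, got %d", n)
  if (is.null(outcome_col))
    outcome_col <- if (outcome_family == "binary") "hyperuricemia" else "urate"
  x <- ph$exposure
  y <- ph[[outcome_col]]
  if (is.null(x) || is.null(y)) stop2("phenotype table lacks exposure/outcome")

  mono <- apply(G, 2L, function(col) stats::var(col) == 0)
  if (any(mono)) {
    warn2("excluding %d monomorphic SNP(s): %s", sum(mono),
          paste(colnames(G)[mono], collapse = ", "))
    G <- G[, !mono, drop = FALSE]
  }
  if (ncol(G) == 0L) stop2("no polymorphic SNPs left")

  # Exposure regressions: vectorised simple OLS across SNP columns.
  gc <- sweep(G, 2L, colMeans(G))
  sxx <- colSums(gc^2)
  xc <- x - mean(x)
  sxy <- colSums(gc * xc)
  beta_exp <- sxy / sxx
  rss <- sum(xc^2) - beta_exp * sxy
  se_exp <- sqrt(pmax(rss, 0) / (n - 2) / sxx)

  # Outcome regressions per SNP.
  if (outcome_family == "binary") {
    fits <- apply(G, 2L, function(col) {
      fit <- stats::glm.fit(cbind(1, col), y, family = stats::binomial())
      cf <- fit$coefficients[2L]
      # SE from the usual GLM covariance (X' W X)^{-1}.
      w <- fit$weights
      XtWX <- crossprod(cbind(1, col) * sqrt(w))
      se <- sqrt(diag(solve(XtWX)))[2L]
      c(cf, se)
    })
  } else {
    yc <- y - mean(y)
    syg <- colSums(gc * yc)
    b <- syg / sxx
    rss_y <- sum(yc^2) - b * syg
    fits <- rbind(b, sqrt(pmax(rss_y, 0) / (n - 2) / sxx))
  }

  keep <- colnames(G)
  meta <- g$meta[match(keep, g$meta$snp_id), ]
  out <- data.frame(snp_id = keep,
                    beta_exp = beta_exp, se_exp = se_exp,
                    beta_out = fits[1L, ], se_out = fits[2L, ],
                    eaf = meta$eaf, row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("snp_summary", "data.frame")
  out
}
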