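#' Two-stage Mendelian randomization estimate
#'
#' Stage one regresses the exposure on the genetic risk score (plus
#' covariates) by least squares; stage two regresses the outcome on the
#' stage-one fitted exposure (plus the same covariates), logistic for a
#' binary outcome and linear for a continuous one. The causal estimate is
#' the second-stage coefficient on the fitted exposure.
#'
#' The default standard error is the second-stage model SE, which ignores
#' first-stage sampling uncertainty (the conventional practice for
#' GRS-based two-stage analyses); set `n_boot > 0` for a nonparametric
#' bootstrap SE that propagates both stages. The first-stage F-statistic
#' is always computed; estimates with F below 10 carry a weak-instrument
#' warning and a `weak_instrument` flag.
#'
#' @param grs Genetic risk score vector.
#' @param exposure Exposure vector (hours/day, or a 0/1 liability
#'   indicator).
#' @param outcome Outcome vector (0/1 or continuous).
#' @param covariates Optional covariate data.frame/matrix used in both
#'   stages.
#' @param outcome_family `"binary"` or `"continuous"`.
#' @param n_boot Bootstrap replicates for the SE (0 = model-based SE).
#' @param seed Seed for the bootstrap.
#' @return An `mr_estimate` with extras `F_stat`, `r2`,
#'   `weak_instrument`, `stage1_beta`.
#' @export
mr_two_stage <- function(grs, exposure, outcome, covariates = NULL,
                         outcome_family = c("binary", "continuous"),
                         n_boot = 0, seed = 1L) {
  outcome_family <- match.arg(outcome_family)
  n <- length(outcome)
  stopifnot(length(grs) == n, length(exposure) == n)
  covs <- covariate_matrix(covariates, n)
  strength <- instrument_strength(grs, exposure, covariates)
  if (strength$weak)
    warn2("weak instrument: first-stage F = %.2f < 10; estimate unreliable",
          strength$F_stat)

  est <- two_stage_fit(grs, exposure, outcome, covs, outcome_family)
  se <- est["se"]
  if (n_boot > 0) {
    set.seed(seed)
    boots <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      two_stage_fit(grs[idx], exposure[idx], outcome[idx],
                    covs[idx, , drop = FALSE], outcome_family)["beta"]
    }, numeric(1))
    se <- stats::sd(boots)
  }
  mr_estimate("two_stage", unname(est["beta"]), unname(se),
              n_snps = attr(grs, "n_snps_used") %||% NA_integer_,
              outcome_family = outcome_family,
              extra = list(F_stat = strength$F_stat, r2 = strength$r2,
                           weak_instrument = strength$weak,
                           stage1_beta = unname(est["stage1_beta"])))
}

two_stage_fit <- function(grs, exposure, outcome, covs, outcome_family) {
  X1 <- cbind(1, covs, grs = grs)
  fit1 <- stats::lm.fit(X1, exposure)
  xhat <- exposure - fit1$residuals
  X2 <- cbind(1, xhat = xhat, covs)
  if (outcome_family == "binary") {
    fit2 <- stats::glm.fit(X2, outcome, family = stats::binomial())
    V <- solve(crossprod(X2 * sqrt(fit2$weights)))
    se <- sqrt(V[2, 2])
  } else {
    fit2 <- stats::lm.fit(X2, outcome)
    s2 <- sum(fit2$residuals^2) / (length(outcome) - ncol(X2))
    V <- s2 * chol2inv(qr.R(qr(X2)))
    se <- sqrt(V[2, 2])
  }
  c(beta = unname(fit2$coefficients[2]), se = se,
    stage1_beta = unname(fit1$coefficients[ncol(X1)]))
}

#' Wald ratio estimate from a single instrument
#'
#' Ratio of the instrument-outcome to the instrument-exposure coefficient
#' with the full (second-order) delta-method standard error
#' `sqrt(se_out^2 / beta_exp^2 + beta_out^2 se_exp^2 / beta_exp^4)`.
#'
#' @param beta_out,se_out Instrument-outcome association and SE.
#' @param beta_exp,se_exp Instrument-exposure association and SE
#'   (`beta_exp` must be nonzero).
#' @param outcome_family Passed through to the estimate label.
#' @return An `mr_estimate` with method `"wald_ratio"`.
#' @export
mr_wald_ratio <- function(beta_out, se_out, beta_exp, se_exp,
                          outcome_family = "binary") {
  if (beta_exp == 0) stop2("beta_exp is zero: the Wald ratio is undefined")
  beta <- beta_out / beta_exp
  se <- sqrt(se_out^2 / beta_exp^2 + beta_out^2 * se_exp^2 / beta_exp^4)
  mr_estimate("wald_ratio", beta, se, n_snps = 1L,
              outcome_family = outcome_family)
}

check_snp_summary <- function(s, min_snps, caller) {
  stopifnot(is.data.frame(s))
  need <- c("beta_exp", "se_exp", "beta_out", "se_out")
  miss <- setdiff(need, names(s))
  if (length(miss)) stop2("summary table lacks columns: %s",
                          paste(miss, collapse = ", "))
  if (any(s$se_exp <= 0) || any(s$se_out <= 0))
    stop2("standard errors must be strictly positive")
  if (nrow(s) < min_snps)
    stop2("%s needs at least %d SNPs, got %d%s", caller, min_snps, nrow(s),
          if (min_snps == 2) " (use mr_wald_ratio for a single instrument)"
          else "")
  invisible(s)
}

#' Inverse-variance weighted estimator with Cochran's Q
#'
#' Fixed-effect weighted regression of SNP-outcome on SNP-exposure effects
#' through the origin, weights `1/se_out^2`:
#' `beta = sum(w bx by) / sum(w bx^2)`, `SE = 1/sqrt(sum(w bx^2))`.
#' Heterogeneity is summarised by `Q = sum(w (by - beta bx)^2)` on
#' `n_snps - 1` degrees of freedom.
#'
#' @param s A `snp_summary` data.frame (>= 2 SNPs).
#' @param outcome_family Estimate label.
#' @return List with `estimate` (an `mr_estimate`), `cochran_q`, `q_p`.
#' @export
mr_ivw <- function(s, outcome_family = "binary") {
  check_snp_summary(s, 2L, "mr_ivw")
  w <- 1 / s$se_out^2
  beta <- sum(w * s$beta_exp * s$beta_out) / sum(w * s$beta_exp^2)
  se <- 1 / sqrt(sum(w * s$beta_exp^2))
  q <- sum(w * (s$beta_out - beta * s$beta_exp)^2)
  q_p <- stats::pchisq(q, df = nrow(s) - 1L, lower.tail = FALSE)
  list(estimate = mr_estimate("ivw", beta, se, n_snps = nrow(s),
                              outcome_family = outcome_family),
       cochran_q = q, q_p = q_p)
}

#' MR-Egger regression
#'
#' Weighted regression of SNP-outcome on SNP-exposure effects with a free
#' intercept (weights `1/se_out^2`). Before fitting, every SNP is oriented
#' so its exposure effect is non-negative (flipping the sign of both
#' coordinates), which the intercept's interpretation requires. The slope
#' is the pleiotropy-adjusted causal estimate; an intercept significantly
#' different from zero indicates average directional (horizontal)
#' pleiotropy. Standard errors use the weighted-least-squares fit with the
#' residual dispersion floored at 1.
#'
#' @param s A `snp_summary` data.frame (>= 3 SNPs).
#' @param outcome_family Estimate label.
#' @return List with `estimate` (slope `mr_estimate`), `intercept`,
#'   `intercept_se`, `intercept_p`.
#' @export
mr_egger <- function(s, outcome_family = "binary") {
  check_snp_summary(s, 3L, "mr_egger")
  flip <- sign(s$beta_exp)
  flip[flip == 0] <- 1
  bx <- s$beta_exp * flip
  by <- s$beta_out * flip
  w <- 1 / s$se_out^2
  fit <- stats::lm(by ~ bx, weights = w)
  sm <- summary(fit)
  disp <- max(sm$sigma, 1)  # guard against under-dispersion
  slope <- sm$coefficients["bx", "Estimate"]
  slope_se <- sm$coefficients["bx", "Std. Error"] / sm$sigma * disp
  int <- sm$coefficients["(Intercept)", "Estimate"]
  int_se <- sm$coefficients["(Intercept)", "Std. Error"] / sm$sigma * disp
  list(estimate = mr_estimate("egger", slope, slope_se, n_snps = nrow(s),
                              outcome_family = outcome_family),
       intercept = int, intercept_se = int_se,
       intercept_p = 2 * stats::pnorm(-abs(int / int_se)))
}

#' Weighted median estimator
#'
#' Per-SNP Wald ratios are sorted and the estimate is the value at which
#' the inverse-variance-weighted cumulative weight crosses 50%, with
#' linear interpolation between the bracketing ratios. The estimator is
#' consistent when instruments carrying at least half of the weight are
#' valid. The SE comes from a parametric bootstrap that redraws the
#' summary coefficients from their normal sampling distributions.
#'
#' @param s A `snp_summary` data.frame (>= 3 SNPs).
#' @param n_boot Number of bootstrap draws (default 1000).
#' @param seed Seed for the bootstrap.
#' @param outcome_family Estimate label.
#' @return An `mr_estimate` with method `"weighted_median"`.
#' @export
mr_weighted_median <- function(s, n_boot = 1000, seed = 1L,
                               outcome_family = "binary") {
  check_snp_summary(s, 3L, "mr_weighted_median")
  ratio_w <- s$beta_exp^2 / s$se_out^2  # 1 / first-order ratio variance
  est <- weighted_median_point(s$beta_out / s$beta_exp, ratio_w)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(b) {
    bx <- stats::rnorm(nrow(s), s$beta_exp, s$se_exp)
    by <- stats::rnorm(nrow(s), s$beta_out, s$se_out)
    bx[bx == 0] <- .Machine$double.eps
    weighted_median_point(by / bx, bx^2 / s$se_out^2)
  }, numeric(1))
  mr_estimate("weighted_median", est, stats::sd(boots), n_snps = nrow(s),
              outcome_family = outcome_family)
}

# 50% point of the weighted cumulative distribution of sorted values, with
# linear interpolation between bracketing order statistics.
weighted_median_point <- function(b, w) {
  o <- order(b)
  b <- b[o]
  w <- w[o] / sum(w)
  cs <- cumsum(w) - w / 2
  if (cs[1] >= 0.5) return(b[1])
  if (cs[length(b)] <= 0.5) return(b[length(b)])
  i <- max(which(cs < 0.5))
  b[i] + (b[i + 1] - b[i]) * (0.5 - cs[i]) / (cs[i + 1] - cs[i])
}

#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' Global test: the observed residual sum of squares from leave-one-out
#' inverse-variance-weighted predictions is compared against `n_sim`
#' parametric simulations under the no-pleiotropy model; the global
#' p-value is `(1 + #(sim >= obs)) / (1 + n_sim)` so it can never be
#' exactly zero. Outlier test: each SNP's observed RSS contribution is
#' compared with its simulated distribution, Bonferroni-corrected over
#' SNPs. The corrected estimate re-runs IVW after removing flagged
#' outliers.
#'
#' @param s A `snp_summary` data.frame (>= 4 SNPs).
#' @param n_sim Number of parametric simulations (>= 100).
#' @param seed Seed.
#' @param alpha Significance level for outlier flagging (after Bonferroni).
#' @param outcome_family Estimate label.
#' @return List with `report` (class `pleiotropy_report`: `presso_global_p`,
#'   `presso_outliers`, per-SNP `outlier_p`) and `corrected` (IVW
#'   `mr_estimate` after outlier removal; equals the plain IVW when no
#'   outlier is flagged).
#' @export
mr_presso <- function(s, n_sim = 1000, seed = 1L, alpha = 0.05,
                      outcome_family = "binary") {
  check_snp_summary(s, 4L, "mr_presso")
  if (!is_count(n_sim) || n_sim < 100)
    stop2("n_sim must be at least 100 (got %s)", format(n_sim))
  p <- nrow(s)
  if (p / (1 + n_sim) >= alpha)
    warn2(paste("n_sim = %d is too small to flag any outlier among %d SNPs",
                "at alpha = %g after Bonferroni (p-value floor %.3g);",
                "increase n_sim"),
          n_sim, p, alpha, p / (1 + n_sim))
  w <- 1 / s$se_out^2
  bx <- s$beta_exp; by <- s$beta_out

  # Leave-one-out IVW slopes, closed form from totals.
  Sxy <- sum(w * bx * by); Sxx <- sum(w * bx^2)
  loo <- (Sxy - w * bx * by) / (Sxx - w * bx^2)
  obs_rss_j <- w * (by - loo * bx)^2
  obs_rss <- sum(obs_rss_j)

  set.seed(seed)
  # Parametric draws under the no-pleiotropy model: bx* ~ N(bx, se_exp),
  # by* ~ N(loo_j * bx_j, se_out).
  bxs <- matrix(stats::rnorm(n_sim * p, rep(bx, each = n_sim),
                             rep(s$se_exp, each = n_sim)), n_sim, p)
  bys <- matrix(stats::rnorm(n_sim * p, rep(loo * bx, each = n_sim),
                             rep(s$se_out, each = n_sim)), n_sim, p)
  W <- matrix(w, n_sim, p, byrow = TRUE)
  Sxy_s <- rowSums(W * bxs * bys)
  Sxx_s <- rowSums(W * bxs^2)
  # Leave-one-out slope per simulation and SNP (vector recycling is
  # column-wise, aligning each row sum with its simulation).
  loo_s <- (Sxy_s - W * bxs * bys) / (Sxx_s - W * bxs^2)
  sim_rss_j <- W * (bys - loo_s * bxs)^2
  sim_rss <- rowSums(sim_rss_j)

  global_p <- (1 + sum(sim_rss >= obs_rss)) / (1 + n_sim)
  outlier_p <- vapply(seq_len(p), function(j)
    (1 + sum(sim_rss_j[, j] >= obs_rss_j[j])) / (1 + n_sim), numeric(1))
  flagged <- which(outlier_p * p < alpha)
  outliers <- s$snp_id[flagged] %||% as.character(flagged)
  if (length(flagged) == p)
    stop2("all %d SNPs flagged as outliers: no corrected estimate possible", p)
  corrected_tab <- if (length(flagged)) s[-flagged, , drop = FALSE] else s
  corrected <- mr_ivw(corrected_tab, outcome_family)$estimate
  corrected$method <- "presso_corrected"
  report <- structure(list(presso_global_p = global_p,
                           presso_outliers = outliers,
                           outlier_p = stats::setNames(outlier_p, s$snp_id),
                           obs_rss = obs_rss),
                      class = "pleiotropy_report")
  list(report = report, corrected = corrected)
}

#' @export
print.pleiotropy_report <- function(x, ...) {
  cat(sprintf("MR-PRESSO global p = %.4g; %d outlier(s)%s\n",
              x$presso_global_p, length(x$presso_outliers),
              if (length(x$presso_outliers))
                paste0(": ", paste(x$presso_outliers, collapse = ", "))
              else ""))
  invisible(x)
}

#' Rescale a binary-exposure estimate per doubling of genetic liability
#'
#' Estimates computed against a 0/1 exposure indicator are multiplied by
#' `ln 2` so they read as the effect of each doubling of the genetic
#' liability for the exposure trait. The z-score, and hence the p-value,
#' is unchanged.
#'
#' @param e An `mr_estimate` on the `per_hour` (per-unit) scale.
#' @return The rescaled `mr_estimate` with
#'   `scale_note = "per_doubling_of_liability"`.
#' @export
rescale_binary_exposure <- function(e) {
  stopifnot(inherits(e, "mr_estimate"))
  if (identical(e$scale_note, "per_doubling_of_liability"))
    stop2("estimate already rescaled per doubling of liability")
  k <- log(2)
  e$beta <- e$beta * k
  e$se <- e$se * k
  e$ci_low <- e$ci_low * k
  e$ci_high <- e$ci_high * k
  e$scale_note <- "per_doubling_of_liability"
  e
}

#' Bonferroni significance flags
#'
#' Flags p-values below `alpha / m`; the raw p-values are not modified.
#'
#' @param p_values Numeric vector of p-values.
#' @param m Number of tests in the family (>= 1).
#' @param alpha Family-wise level (default 0.05).
#' @return Logical vector; the threshold is attached as attribute
#'   `threshold`.
#' @export
bonferroni_flag <- function(p_values, m, alpha = 0.05) {
  if (!is_count(m)) stop2("m must be a positive integer")
  thr <- alpha / m
  structure(p_values < thr, threshold = thr)
}
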