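#' Classify hyperuricemia from serum urate using sex-specific thresholds
#'
#' Hyperuricemia is defined as serum urate at or above 420 micromol/L in
#' men and 360 micromol/L in women; boundary values count as cases.
#'
#' @param urate Serum urate in micromol/L (non-negative).
#' @param sex Character or factor, `"male"`/`"female"`.
#' @return Integer vector of 0/1; `NA` where urate or sex is missing
#'   (records to be excluded in a complete-case analysis). The number of
#'   incomplete records is attached as attribute `n_excluded`.
#' @export
classify_hyperuricemia <- function(urate, sex) {
  sex <- as.character(sex)
  if (length(urate) != length(sex))
    stop2("urate and sex differ in length")
  bad_sex <- !(sex %in% c("male", "female") | is.na(sex))
  if (any(bad_sex)) stop2("unknown sex label: %s",
                          paste(unique(sex[bad_sex]), collapse = ", "))
  if (any(urate < 0, na.rm = TRUE)) stop2("negative urate value")
  thr <- ifelse(sex == "male", 420, 360)
  out <- as.integer(urate >= thr)
  out[is.na(urate) | is.na(sex)] <- NA_integer_
  attr(out, "n_excluded") <- sum(is.na(out))
  out
}

#' Categorize integer sleep duration into the five study groups
#'
#' Self-reported sleep duration (integer hours per day) is mapped to the
#' categories `<=5`, `6`, `7`, `8`, `>=9`, with 7 h/day the reference.
#'
#' @param hours Non-negative integer vector of hours per day.
#' @return A factor with levels `c("7", "<=5", "6", "8", ">=9")` (reference
#'   first, as required for model fitting).
#' @export
categorize_sleep <- function(hours) {
  ok <- is.na(hours) | (hours >= 0 & hours == round(hours))
  if (!all(ok)) stop2("sleep hours must be non-negative integers (got %s)",
                      paste(utils::head(hours[!ok], 3), collapse = ", "))
  lab <- ifelse(hours <= 5, "<=5",
         ifelse(hours >= 9, ">=9", as.character(hours)))
  factor(lab, levels = c("7", "<=5", "6", "8", ">=9"))
}

#' Odds ratio from a 2x2 contingency table
#'
#' Closed-form odds ratio with a Wald confidence interval from the standard
#' error of the log odds ratio, `SE = sqrt(1/a + 1/b + 1/c + 1/d)`.
#'
#' @param cases_exposed,noncases_exposed,cases_ref,noncases_ref Cell
#'   counts; all four must be strictly positive.
#' @param level Confidence level (default 0.95).
#' @return An `or_estimate`: list with `or_value`, `ci_low`, `ci_high`,
#'   `p_value`, `se_log_or`, `model_label = "univariable"`.
#' @export
contingency_or <- function(cases_exposed, noncases_exposed,
                           cases_ref, noncases_ref, level = 0.95) {
  cells <- c(cases_exposed, noncases_exposed, cases_ref, noncases_ref)
  if (any(cells < 0)) stop2("negative cell count")
  if (any(cells == 0))
    stop2(paste("zero cell in the 2x2 table; the odds ratio is undefined.",
                "Apply a continuity strategy explicitly (e.g. add 0.5 to",
                "every cell) before calling contingency_or"))
  or <- (cases_exposed * noncases_ref) / (noncases_exposed * cases_ref)
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- list(or_value = or,
              ci_low = exp(log(or) - z * se),
              ci_high = exp(log(or) + z * se),
              p_value = 2 * stats::pnorm(-abs(log(or) / se)),
              se_log_or = se,
              model_label = "univariable")
  class(out) <- "or_estimate"
  out
}

#' @export
print.or_estimate <- function(x, ...) {
  cat(sprintf("OR %.2f (95%% CI %.2f-%.2f), p = %.3g [%s]\n",
              x$or_value, x$ci_low, x$ci_high, x$p_value, x$model_label))
  invisible(x)
}

#' Category-wise odds ratios for hyperuricemia by sleep-duration group
#'
#' Fits a maximum-likelihood logistic regression of hyperuricemia on the
#' five-level sleep-duration category (reference 7 h/day), optionally
#' adjusted for covariates, and reports exponentiated category coefficients
#' with Wald confidence intervals. With an empty adjustment set this
#' reproduces the closed-form contingency odds ratios.
#'
#' @param ph Data frame with `hyperuricemia` (0/1) and either
#'   `sleep_category` (factor from [categorize_sleep()]) or `sleep_hours`.
#' @param adjust Character vector of covariate column names (may be empty).
#' @param level Confidence level.
#' @return Data frame with one row per non-reference category: `category`,
#'   `n`, `n_cases`, `or_value`, `ci_low`, `ci_high`, `p_value`,
#'   `model_label`. The complete-case exclusion count is attached as
#'   attribute `n_excluded`.
#' @export
fit_category_or <- function(ph, adjust = character(), level = 0.95) {
  if (is.null(ph$sleep_category)) {
    if (is.null(ph$sleep_hours)) stop2("need sleep_category or sleep_hours")
    ph$sleep_category <- categorize_sleep(ph$sleep_hours)
  }
  if (is.null(ph$hyperuricemia)) stop2("need a binary `hyperuricemia` column")
  missing_cov <- setdiff(adjust, names(ph))
  if (length(missing_cov))
    stop2("covariates not found: %s", paste(missing_cov, collapse = ", "))
  dat <- ph[, c("hyperuricemia", "sleep_category", adjust), drop = FALSE]
  cc <- stats::complete.cases(dat)
  n_excluded <- sum(!cc)
  if (n_excluded > 0)
    message(sprintf("complete-case analysis: %d record(s) excluded", n_excluded))
  dat <- dat[cc, , drop = FALSE]
  fml <- stats::reformulate(c("sleep_category", adjust),
                            response = "hyperuricemia")
  fit <- stats::glm(fml, data = dat, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-12, maxit = 50))
  cf <- summary(fit)$coefficients
  idx <- grep("^sleep_category", rownames(cf))
  if (any(!is.finite(cf[idx, 1])) || any(abs(cf[idx, 1]) > 15)) {
    bad <- sub("^sleep_category", "", rownames(cf)[idx])[
      !is.finite(cf[idx, 1]) | abs(cf[idx, 1]) > 15]
    stop2("separation: non-finite odds ratio for category %s",
          paste(bad, collapse = ", "))
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  cats <- sub("^sleep_category", "", rownames(cf)[idx])
  tab <- table(dat$sleep_category, dat$hyperuricemia)
  out <- data.frame(
    category = cats,
    n = as.integer(rowSums(tab)[cats]),
    n_cases = as.integer(tab[cats, "1"]),
    or_value = exp(cf[idx, 1]),
    ci_low = exp(cf[idx, 1] - z * cf[idx, 2]),
    ci_high = exp(cf[idx, 1] + z * cf[idx, 2]),
    p_value = cf[idx, 4],
    model_label = if (length(adjust)) "multivariable" else "univariable",
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- n_excluded
  attr(out, "fit") <- fit
  out
}

#' Specification for a restricted cubic spline
#'
#' @param n_knots Number of knots (default 4, as in the dose-response
#'   analysis this package reproduces).
#' @param knot_positions Optional explicit knot locations (hours),
#'   strictly increasing. If `NULL`, knots are placed at the 5th, 35th,
#'   65th and 95th percentiles of the observed exposure (the standard
#'   quantile convention for 4 knots).
#' @param reference_value Exposure value the dose-response curve is
#'   anchored at (odds ratio 1); default 7 hours/day.
#' @return A `spline_spec` list.
#' @export
spline_spec <- function(n_knots = 4, knot_positions = NULL,
                        reference_value = 7) {
  if (!is_count(n_knots) || n_knots < 3) stop2("need at least 3 knots")
  if (!is.null(knot_positions)) {
    if (length(knot_positions) != n_knots)
      stop2("knot_positions length must equal n_knots")
    if (any(diff(knot_positions) <= 0))
      stop2("knots must be strictly increasing")
  }
  structure(list(n_knots = as.integer(n_knots),
                 knot_positions = knot_positions,
                 reference_value = reference_value),
            class = "spline_spec")
}

default_knot_quantiles <- function(k) {
  # Standard outer/inner quantile conventions (0.05/0.95 outer knots).
  switch(as.character(k),
         "3" = c(0.1, 0.5, 0.9),
         "4" = c(0.05, 0.35, 0.65, 0.95),
         "5" = c(0.05, 0.275, 0.5, 0.725, 0.95),
         seq(0.05, 0.95, length.out = k))
}

# Resolve knots against data; integer-valued exposures make quantile knots
# collide, in which case coincident knots are moved to distinct observed
# values with a warning.
resolve_knots <- function(x, spec) {
  if (!is.null(spec$knot_positions)) {
    k <- spec$knot_positions
  } else {
    k <- as.numeric(stats::quantile(x, default_knot_quantiles(spec$n_knots),
                                    type = 7))
    if (anyDuplicated(k)) {
      ux <- sort(unique(x))
      m <- length(ux)
      if (m < spec$n_knots)
        stop2("fewer distinct exposure values (%d) than knots (%d)",
              m, spec$n_knots)
      # Map each target knot to the nearest distinct observed value, then
      # force strictly increasing indices (always feasible since m >= k).
      kk <- spec$n_knots
      idx <- vapply(k, function(v) which.min(abs(ux - v)), integer(1))
      # clamp each index to its feasible window, then make them strictly
      # increasing; feasibility is guaranteed because m >= kk
      idx <- pmin(pmax(idx, seq_len(kk)), m - kk + seq_len(kk))
      for (i in seq_len(kk)[-1])
        idx[i] <- max(idx[i], idx[i - 1] + 1L)
      k <- ux[idx]
      warn2("coincident quantile knots moved to distinct observed values: %s",
            paste(format(k), collapse = ", "))
    }
  }
  if (min(k) < min(x) || max(k) > max(x))
    stop2("knots outside the observed exposure range [%g, %g]", min(x), max(x))
  k
}

#' Restricted cubic spline basis (natural cubic, truncated-power form)
#'
#' Builds the classical restricted cubic spline basis: with knots
#' `t_1 < ... < t_k` the basis has `k - 1` columns; the first is `x` and
#' column `j + 1` is
#' \deqn{[(x - t_j)_+^3 - (x - t_{k-1})_+^3 (t_k - t_j)/(t_k - t_{k-1})
#'   + (x - t_k)_+^3 (t_{k-1} - t_j)/(t_k - t_{k-1})] / (t_k - t_1)^2}
#' for `j = 1, ..., k - 2`. The fitted function is linear beyond the outer
#' knots.
#'
#' @param x Numeric exposure vector (at least `n_knots` distinct values,
#'   spanning the knots).
#' @param spec A [spline_spec()].
#' @return Numeric matrix with `n_knots - 1` columns; the resolved knots
#'   are attached as attribute `knots`.
#' @export
rcs_basis <- function(x, spec = spline_spec()) {
  if (length(unique(x)) < 2) stop2("constant exposure: no spread to model")
  knots <- resolve_knots(x, spec)
  k <- length(knots)
  if (length(unique(x)) < k)
    stop2("need at least %d distinct exposure values", k)
  tk <- knots[k]; tk1 <- knots[k - 1]; scale <- (tk - knots[1])^2
  pos3 <- function(u) pmax(u, 0)^3
  B <- matrix(0, length(x), k - 1)
  B[, 1] <- x
  for (j in seq_len(k - 2)) {
    tj <- knots[j]
    B[, j + 1] <- (pos3(x - tj) -
                     pos3(x - tk1) * (tk - tj) / (tk - tk1) +
                     pos3(x - tk) * (tk1 - tj) / (tk - tk1)) / scale
  }
  colnames(B) <- paste0("rcs", seq_len(k - 1))
  attr(B, "knots") <- knots
  B
}

#' Restricted-cubic-spline dose-response curve for hyperuricemia
#'
#' Fits a logistic regression of hyperuricemia on the restricted cubic
#' spline basis of sleep duration (plus optional covariates) and reports
#' the fitted dose-response as odds ratios relative to the reference
#' exposure, with pointwise delta-method confidence bands on the
#' linear-predictor contrast. The odds ratio at the reference value is
#' exactly 1 with a zero-width interval.
#'
#' @param ph Data frame with `hyperuricemia` and a continuous exposure
#'   column (`exposure` or `sleep_hours`).
#' @param spec A [spline_spec()].
#' @param adjust Covariate column names.
#' @param grid Exposure values to evaluate the curve on; defaults to an
#'   even grid over the observed range.
#' @param level Confidence level.
#' @return Data frame `hours`, `or`, `ci_low`, `ci_high` (class
#'   `rcs_curve`), with the fitted `glm` and knots as attributes.
#' @export
rcs_dose_response <- function(ph, spec = spline_spec(), adjust = character(),
                              grid = NULL, level = 0.95) {
  x <- ph$exposure %||% ph$sleep_hours
  if (is.null(x)) stop2("need an `exposure` or `sleep_hours` column")
  if (is.null(ph$hyperuricemia)) stop2("need a `hyperuricemia` column")
  dat <- data.frame(y = ph$hyperuricemia, x = x)
  if (length(adjust)) dat <- cbind(dat, ph[, adjust, drop = FALSE])
  cc <- stats::complete.cases(dat)
  if (any(!cc)) message(sprintf("complete-case analysis: %d excluded", sum(!cc)))
  dat <- dat[cc, , drop = FALSE]
  B <- rcs_basis(dat$x, spec)
  knots <- attr(B, "knots")
  ref <- spec$reference_value
  if (ref < min(dat$x) || ref > max(dat$x))
    stop2("reference value %g outside the exposure range", ref)
  covs <- if (length(adjust))
    covariate_matrix(dat[, adjust, drop = FALSE], nrow(dat)) else NULL
  X <- cbind(1, B, covs)
  fit <- stats::glm.fit(X, dat$y, family = stats::binomial())
  V <- tryCatch(solve(crossprod(X * sqrt(fit$weights))),
                error = function(e) stop2("singular spline fit: %s",
                                          conditionMessage(e)))
  if (is.null(grid))
    grid <- seq(min(dat$x), max(dat$x), length.out = 101)
  grid <- sort(unique(c(grid, ref)))
  # Contrast of spline columns against the reference; covariates cancel.
  Bg <- rcs_eval(grid, knots)
  Br <- rcs_eval(ref, knots)
  Cmat <- cbind(0, sweep(Bg, 2L, as.numeric(Br)),
                matrix(0, length(grid), if (is.null(covs)) 0 else ncol(covs)))
  est <- as.vector(Cmat %*% fit$coefficients)
  se <- sqrt(rowSums((Cmat %*% V) * Cmat))
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- data.frame(hours = grid, or = exp(est),
                    ci_low = exp(est - z * se), ci_high = exp(est + z * se))
  class(out) <- c("rcs_curve", "data.frame")
  attr(out, "knots") <- knots
  attr(out, "coefficients") <- fit$coefficients
  out
}

# Evaluate the RCS basis at arbitrary points given fixed knots.
rcs_eval <- function(x, knots) {
  k <- length(knots)
  tk <- knots[k]; tk1 <- knots[k - 1]; scale <- (tk - knots[1])^2
  pos3 <- function(u) pmax(u, 0)^3
  B <- matrix(0, length(x), k - 1)
  B[, 1] <- x
  for (j in seq_len(k - 2)) {
    tj <- knots[j]
    B[, j + 1] <- (pos3(x - tj) -
                     pos3(x - tk1) * (tk - tj) / (tk - tk1) +
                     pos3(x - tk) * (tk1 - tj) / (tk - tk1)) / scale
  }
  B
}

#' Descriptive comparison of characteristics across sleep categories
#'
#' One-way ANOVA for continuous characteristics and chi-square tests for
#' categorical ones, across the five sleep-duration groups.
#'
#' @param ph Phenotype data frame containing `sleep_category` (or
#'   `sleep_hours`) and the columns named in `vars`.
#' @param vars Character vector of characteristic columns to compare.
#' @return Data frame `variable`, `type`, `statistic`, `p_value`.
#' @export
describe_by_category <- function(ph, vars) {
  if (is.null(ph$sleep_category))
    ph$sleep_category <- categorize_sleep(ph$sleep_hours)
  rows <- lapply(vars, function(v) {
    x <- ph[[v]]
    if (is.null(x)) stop2("column `%s` not found", v)
    if (is.numeric(x)) {
      fit <- stats::aov(x ~ ph$sleep_category)
      s <- summary(fit)[[1]]
      data.frame(variable = v, type = "continuous",
                 statistic = s$`F value`[1], p_value = s$`Pr(>F)`[1])
    } else {
      tst <- suppressWarnings(stats::chisq.test(table(x, ph$sleep_category)))
      data.frame(variable = v, type = "categorical",
                 statistic = unname(tst$statistic), p_value = tst$p.value)
    }
  })
  do.call(rbind, rows)
}
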