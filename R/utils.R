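# Internal helpers shared across modules.

# Derive a reproducible child seed from a master seed and a stream index.
# Keeps every derived seed a valid 32-bit integer.
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(as.numeric(seed)) * 48271 + 9973 * stream) %% 2147483629L)
}

stop2 <- function(...) stop(sprintf(...), call. = FALSE)
warn2 <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

check_fraction <- function(x, name, lo = 0, hi = 1, open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    if (open) (x > lo && x < hi) else (x >= lo && x <= hi)
  if (!ok) stop2("`%s` must be a single number in %s%g, %g%s, got %s",
                 name, if (open) "(" else "[", lo, hi,
                 if (open) ")" else "]", format(x))
  invisible(x)
}

# Wald-type normal confidence interval and two-sided p from (beta, se).
wald_ci <- function(beta, se, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(ci_low = beta - z * se, ci_high = beta + z * se,
       p_value = 2 * stats::pnorm(-abs(beta / se)))
}

# Build an mr_estimate record (shared result container for all estimators).
mr_estimate <- function(method, beta, se, n_snps = NA_integer_,
                        scale_note = "per_hour", outcome_family = "binary",
                        extra = list()) {
  ci <- wald_ci(beta, se)
  out <- c(list(method = method, beta = beta, se = se,
                ci_low = ci$ci_low, ci_high = ci$ci_high,
                p_value = ci$p_value, n_snps = n_snps,
                scale_note = scale_note, outcome_family = outcome_family),
           extra)
  class(out) <- "mr_estimate"
  out
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("MR estimate [%s], scale: %s\n", x$method, x$scale_note))
  cat(sprintf("  beta = %.4f (SE %.4f), 95%% CI [%.4f, %.4f], p = %.3g\n",
              x$beta, x$se, x$ci_low, x$ci_high, x$p_value))
  if (identical(x$outcome_family, "binary")) {
    cat(sprintf("  OR = %.3f (95%% CI %.3f-%.3f)\n",
                exp(x$beta), exp(x$ci_low), exp(x$ci_high)))
  }
  if (!is.na(x$n_snps)) cat(sprintf("  instruments: %d SNPs\n", x$n_snps))
  invisible(x)
}

# Covariate handling: accept NULL, a data.frame, or a numeric matrix/vector;
# return a numeric model matrix (no intercept) or NULL.
covariate_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(NULL)
  if (is.numeric(covariates) && is.null(dim(covariates))) {
    covariates <- matrix(covariates, ncol = 1L,
                         dimnames = list(NULL, "cov1"))
  }
  if (is.data.frame(covariates)) {
    mm <- stats::model.matrix(~ ., data = covariates)[, -1L, drop = FALSE]
  } else {
    mm <- as.matrix(covariates)
    if (is.null(colnames(mm))) colnames(mm) <- paste0("cov", seq_len(ncol(mm)))
  }
  if (nrow(mm) != n) stop2("covariates have %d rows, expected %d", nrow(mm), n)
  storage.mode(mm) <- "double"
  mm
}
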