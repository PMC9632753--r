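test_that("Wald ratio and its delta-method SE match hand calculations", {
  e <- mr_wald_ratio(0, 0.01, 0.04, 0.005)
  expect_equal(e$beta, 0)
  e <- mr_wald_ratio(0.02, 0.01, 0.04, 0.005)
  expect_equal(e$beta, 0.5)
  expect_equal(e$se, sqrt(0.0625 + 0.00390625), tolerance = 1e-10)
  expect_equal(e$se, 0.2577, tolerance = 1e-4)
  expect_error(mr_wald_ratio(0.02, 0.01, 0, 0.005), "zero")
})

test_that("single-instrument two-stage equals the Wald ratio (continuous outcome)", {
  set.seed(41)
  n <- 3000
  g <- rbinom(n, 2, 0.3)
  x <- 7 + 0.1 * g + rnorm(n)
  y <- 300 + 5 * x + rnorm(n, sd = 20)
  ts <- mr_two_stage(g, x, y, outcome_family = "continuous")
  s_gx <- summary(lm(x ~ g))$coefficients
  s_gy <- summary(lm(y ~ g))$coefficients
  wr <- s_gy[2, 1] / s_gx[2, 1]
  expect_equal(ts$beta, wr, tolerance = 1e-7)
})

test_that("IVW solves the origin-through weighted least squares exactly", {
  s <- toy_summary_common_ratio(b = 0.4)
  res <- mr_ivw(s)
  expect_equal(res$estimate$beta, 0.4, tolerance = 1e-12)
  expect_equal(res$cochran_q, 0, tolerance = 1e-20)
  expect_equal(res$q_p, 1)

  # 3-SNP toy table vs a brute-force weighted normal-equations solve
  s3 <- data.frame(beta_exp = c(0.02, 0.05, 0.03),
                   se_exp = c(0.004, 0.005, 0.004),
                   beta_out = c(0.011, 0.018, 0.004),
                   se_out = c(0.01, 0.012, 0.009))
  res3 <- mr_ivw(s3)
  w <- 1 / s3$se_out^2
  brute <- solve(t(s3$beta_exp) %*% diag(w) %*% s3$beta_exp,
                 t(s3$beta_exp) %*% diag(w) %*% s3$beta_out)
  expect_equal(res3$estimate$beta, as.numeric(brute), tolerance = 1e-10)
  wls <- lm(beta_out ~ 0 + beta_exp, data = s3, weights = w)
  expect_equal(res3$estimate$beta, unname(coef(wls)), tolerance = 1e-10)

  expect_error(mr_ivw(s3[1, ]), "wald_ratio")
})

test_that("IVW equals the inverse-variance meta-analysis of Wald ratios", {
  s <- sim_summary_linear(10, slope = 0.1, seed = 2)
  ratios <- s$beta_out / s$beta_exp
  w1 <- s$beta_exp^2 / s$se_out^2        # first-order ratio weights
  meta <- sum(w1 * ratios) / sum(w1)
  expect_equal(mr_ivw(s)$estimate$beta, meta, tolerance = 1e-10)
})

test_that("Egger regression separates slope from directional pleiotropy", {
  s <- toy_summary_common_ratio(b = 0.3)
  res <- mr_egger(s)
  expect_equal(res$intercept, 0, tolerance = 1e-10)
  expect_equal(res$estimate$beta, 0.3, tolerance = 1e-8)

  s_shift <- s
  s_shift$beta_out <- s_shift$beta_out + 0.01
  res2 <- mr_egger(s_shift)
  expect_equal(res2$intercept, 0.01, tolerance = 1e-8)
  expect_equal(res2$estimate$beta, 0.3, tolerance = 1e-8)

  # orientation invariance: jointly flipping any SNP leaves the fit unchanged
  s_flip <- s_shift
  s_flip$beta_exp[2] <- -s_flip$beta_exp[2]
  s_flip$beta_out[2] <- -s_flip$beta_out[2]
  res3 <- mr_egger(s_flip)
  expect_equal(res3$estimate$beta, res2$estimate$beta, tolerance = 1e-12)
  expect_equal(res3$intercept, res2$intercept, tolerance = 1e-12)

  expect_error(mr_egger(s[1:2, ]), "at least 3")
})

test_that("Egger slope collapses to IVW when the intercept is constrained to zero", {
  s <- sim_summary_linear(15, slope = 0.08, seed = 3)
  w <- 1 / s$se_out^2
  constrained <- unname(coef(lm(beta_out ~ 0 + beta_exp, data = s,
                                weights = w)))
  expect_equal(mr_ivw(s)$estimate$beta, constrained, tolerance = 1e-10)
})

test_that("weighted median interpolates the 50% point of the weight distribution", {
  s <- toy_summary_common_ratio(b = 0.25)
  wm <- mr_weighted_median(s, n_boot = 50, seed = 1)
  expect_equal(wm$beta, 0.25, tolerance = 1e-10)

  s3 <- data.frame(beta_exp = c(1, 1, 1), se_exp = rep(0.01, 3),
                   beta_out = c(0.1, 0.2, 0.9), se_out = rep(0.1, 3))
  wm3 <- mr_weighted_median(s3, n_boot = 50, seed = 1)
  expect_equal(wm3$beta, 0.2, tolerance = 1e-10)
  expect_error(mr_weighted_median(s3[1:2, ]), "at least 3")
})

test_that("weighted median resists a minority of invalid instruments", {
  wins <- vapply(1:40, function(r) {
    s <- sim_summary_linear(15, slope = 0.1, seed = 5000 + r)
    bad <- 1:5                        # <50% of weight carries pleiotropy
    s$beta_out[bad] <- s$beta_out[bad] + 0.05
    wm <- mr_weighted_median(s, n_boot = 10, seed = r)
    ivw <- mr_ivw(s)$estimate
    abs(wm$beta - 0.1) < abs(ivw$beta - 0.1)
  }, logical(1))
  expect_gte(mean(wins), 0.8)
})

test_that("estimators are invariant to SNP input order", {
  s <- sim_summary_linear(12, slope = 0.05, seed = 9)
  perm <- sample(nrow(s))
  sp <- s[perm, ]
  expect_equal(mr_ivw(s)$estimate$beta, mr_ivw(sp)$estimate$beta,
               tolerance = 1e-12)
  expect_equal(mr_egger(s)$estimate$beta, mr_egger(sp)$estimate$beta,
               tolerance = 1e-12)
  expect_equal(mr_weighted_median(s, n_boot = 5, seed = 4)$beta,
               mr_weighted_median(sp, n_boot = 5, seed = 4)$beta,
               tolerance = 1e-12)
})

test_that("MR-PRESSO is calibrated under homogeneity and rejects bad inputs", {
  expect_error(mr_presso(sim_summary_linear(10, 0.1), n_sim = 0), "at least 100")
  expect_error(mr_presso(sim_summary_linear(3, 0.1), n_sim = 200), "at least 4")
  ps <- vapply(1:20, function(r) {
    s <- sim_summary_linear(15, slope = 0.1, seed = 300 + r)
    mr_presso(s, n_sim = 400, seed = r)$report$presso_global_p
  }, numeric(1))
  # roughly uniform: no mass collapse at either end
  expect_gt(mean(ps), 0.2)
  expect_lt(mean(ps > 0.05), 1.01)
  expect_gte(mean(ps > 0.05), 0.8)
})

test_that("MR-PRESSO flags a strong spike-in outlier and reduces average bias", {
  err_raw <- err_cor <- numeric(20); flagged <- logical(20)
  for (r in 1:20) {
    s <- sim_summary_linear(21, slope = 0.1, gamma = 0.05,
                            se_exp = 0.002, se_out = 0.004, seed = 1100 + r)
    # SNP 1 carries a direct effect 10x its causal contribution
    s$beta_out[1] <- s$beta_out[1] + 10 * 0.1 * s$beta_exp[1]
    res <- mr_presso(s, n_sim = 1000, seed = r)
    flagged[r] <- "s001" %in% res$report$presso_outliers
    err_raw[r] <- abs(mr_ivw(s)$estimate$beta - 0.1)
    err_cor[r] <- abs(res$corrected$beta - 0.1)
  }
  expect_gte(mean(flagged), 0.95)
  expect_lt(mean(err_cor), mean(err_raw))
})

test_that("two-stage MR removes confounding bias that the naive regression keeps", {
  cover <- logical(30); naive_sig <- logical(30)
  for (r in 1:30) {
    co <- simulate_cohort(sim_config(
      n_samples = 4000, n_snps = 20, causal_shape = "null",
      confounder_effect_exposure = 0.5, confounder_effect_outcome = 1,
      seed = 7000 + r))
    ph <- co$phenotypes
    grs <- build_grs(co$genotypes)
    ts <- mr_two_stage(grs, ph$exposure, ph$hyperuricemia)
    cover[r] <- ts$ci_low <= 0 && ts$ci_high >= 0
    naive <- summary(glm(hyperuricemia ~ exposure, data = ph,
                         family = binomial()))$coefficients
    naive_sig[r] <- naive[2, 4] < 0.05
  }
  expect_gte(mean(cover), 0.85)          # two-stage CI covers the null
  expect_gte(mean(naive_sig), 0.9)       # observational estimate is biased
})

test_that("doubling-of-liability rescaling preserves z-scores exactly", {
  e <- slumr:::mr_estimate("two_stage", beta = 1.0, se = 0.3)
  r <- rescale_binary_exposure(e)
  expect_equal(r$beta, log(2), tolerance = 1e-12)
  expect_equal(r$beta / r$se, e$beta / e$se, tolerance = 1e-12)
  expect_equal(r$p_value, e$p_value, tolerance = 1e-12)
  expect_identical(r$scale_note, "per_doubling_of_liability")
  expect_error(rescale_binary_exposure(r), "already rescaled")
  e0 <- slumr:::mr_estimate("two_stage", beta = 0, se = 0.3)
  expect_equal(rescale_binary_exposure(e0)$beta, 0)
})

test_that("Bonferroni flags use strict inequality against alpha/m", {
  expect_true(bonferroni_flag(0.01, 3))
  expect_false(bonferroni_flag(0.01, 6))
  expect_false(bonferroni_flag(0.05, 1))
  f <- bonferroni_flag(c(0.001, 0.02, 0.2), 3)
  expect_identical(as.logical(f), c(TRUE, FALSE, FALSE))
  expect_equal(attr(f, "threshold"), 0.05 / 3)
})

test_that("weak instruments trigger a prominent warning", {
  set.seed(55)
  g <- rnorm(300)
  x <- rnorm(300)
  y <- rbinom(300, 1, 0.2)
  expect_warning(mr_two_stage(g, x, y), "weak instrument")
})
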