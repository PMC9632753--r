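test_that("instrument-free residuals are orthogonal to the score", {
  co <- quick_cohort(n = 2000)
  grs <- build_grs(co$genotypes)
  x <- co$phenotypes$exposure
  r <- iv_free_exposure(x, grs)
  expect_lt(abs(sum(r * (grs - mean(grs)))), 1e-6)
  # residual variance shrinks when the score truly affects the exposure
  expect_lt(var(r), var(x))
  # a score with zero in-sample coefficient leaves the covariate fit
  set.seed(2)
  g0 <- rnorm(500)
  x0 <- rnorm(500)
  x0 <- residuals(lm(x0 ~ g0)) + 5           # exposure orthogonal to g0
  r0 <- iv_free_exposure(x0, g0)
  expect_equal(r0, x0 - mean(x0), tolerance = 1e-10)
  expect_error(iv_free_exposure(x0, rep(1, 500)), "constant")
})

test_that("residual stratification cuts near-equal, exhaustive strata", {
  a <- stratify_residuals(c(5, 1, 9, 3, 7, 2, 8, 4, 6), k = 3)
  expect_equal(tabulate(a, 3), c(3, 3, 3))
  expect_error(stratify_residuals(rep(1, 30), k = 3), "identical")
  set.seed(3)
  a2 <- stratify_residuals(rnorm(1e4), k = 3)
  expect_true(all(abs(tabulate(a2, 3) - 1e4 / 3) <= 1))
  expect_error(stratify_residuals(rnorm(10), k = 3, min_n = 10), "need n >=")
  # strata are ordered by residual level
  r <- rnorm(300)
  a3 <- stratify_residuals(r, 3)
  expect_lt(max(r[a3 == 1]), min(r[a3 == 3]))
})

test_that("LACE estimates recover a homogeneous linear slope across strata", {
  covered <- vapply(1:20, function(r) {
    co <- simulate_cohort(sim_config(n_samples = 5000, n_snps = 20,
                                     causal_shape = "linear",
                                     causal_params = list(slope = 0.1),
                                     seed = 900 + r))
    grs <- build_grs(co$genotypes)
    ph <- co$phenotypes
    res <- iv_free_exposure(ph$exposure, grs)
    st <- lace_per_stratum(stratify_residuals(res, 3), grs, ph$exposure,
                           ph$hyperuricemia)
    all(st$lace - 1.96 * st$lace_se <= 0.1 &
        st$lace + 1.96 * st$lace_se >= 0.1)
  }, logical(1))
  # joint coverage of three ~95% intervals
  expect_gte(mean(covered), 0.75)
})

test_that("under a convex truth the LACE increases with the stratum exposure", {
  co <- simulate_cohort(sim_config(n_samples = 100000, n_snps = 20,
                                   causal_shape = "quadratic_u",
                                   causal_params = list(curvature = 0.1),
                                   seed = 42))
  grs <- build_grs(co$genotypes)
  ph <- co$phenotypes
  res <- iv_free_exposure(ph$exposure, grs)
  st <- lace_per_stratum(stratify_residuals(res, 3), grs, ph$exposure,
                         ph$hyperuricemia)
  st <- st[order(st$mean_exposure), ]
  expect_true(all(diff(st$lace) > 0))
})

test_that("a zero score-outcome coefficient gives a zero LACE", {
  set.seed(8)
  n <- 600
  g <- rbinom(n, 2, 0.3)
  x <- 7 + 0.3 * g + rnorm(n)
  y <- rnorm(n)
  y <- residuals(lm(y ~ g))                  # outcome orthogonal to g
  st <- lace_per_stratum(rep(1L, n), g, x, y, outcome_family = "continuous")
  expect_equal(st$lace, 0, tolerance = 1e-10)
})

test_that("a single stratum degenerates to the linear two-stage estimate", {
  set.seed(12)
  n <- 2000
  g <- rbinom(n, 2, 0.3)
  x <- 7 + 0.2 * g + rnorm(n)
  y <- 300 + 4 * x + rnorm(n, sd = 15)
  st <- lace_per_stratum(rep(1L, n), g, x, y, outcome_family = "continuous")
  ts <- mr_two_stage(g, x, y, outcome_family = "continuous")
  expect_equal(st$lace, ts$beta, tolerance = 1e-7)
})

test_that("the piecewise curve is continuous, anchored, and shaped by its slopes", {
  set.seed(5)
  exposure <- rnorm(3000, 7, 1.2)

  # equal LACEs: a single straight line through (reference, 0)
  st <- make_strata(lace = rep(0.2, 3), lace_se = rep(0.05, 3),
                    mean_exposure = c(5.8, 7, 8.2))
  cv <- piecewise_curve(st, exposure, reference_exposure = 7, n_draws = 200)
  expect_equal(cv$log_or, 0.2 * (cv$hours - 7), tolerance = 1e-10)
  at_ref <- cv[cv$hours == 7, ]
  expect_equal(at_ref$log_or, 0)
  expect_equal(at_ref$ci_high - at_ref$ci_low, 0)

  # sign-changing LACEs: U shape with the minimum inside the middle segment
  stu <- make_strata(lace = c(-0.1, 0, 0.1), lace_se = rep(0.05, 3),
                     mean_exposure = c(5, 7, 9))
  cvu <- piecewise_curve(stu, exposure, reference_exposure = 7, n_draws = 200)
  bp <- attr(cvu, "breakpoints")
  xmin <- cvu$hours[which.min(cvu$log_or)]
  expect_gte(xmin, bp[2]); expect_lte(xmin, bp[3])
  # exact continuity: left and right limits agree at every breakpoint
  for (b in bp[2:3]) {
    eps <- 1e-6
    v <- slumr:::piecewise_value(c(b - eps, b, b + eps), bp, stu$lace, 7)
    expect_lt(abs(v[1] - v[2]), 1e-4)
    expect_lt(abs(v[3] - v[2]), 1e-4)
  }
  expect_error(piecewise_curve(make_strata(c(0.1, 0.2), c(0.1, 0.1),
                                           mean_exposure = c(8, 6)),
                               exposure), "ordered")
})

test_that("Cochran's Q on the LACE set matches hand computation", {
  st <- make_strata(lace = c(0.1, 0.1, 0.1), lace_se = rep(0.05, 3))
  q <- cochran_q_test(st)
  expect_equal(q$q, 0, tolerance = 1e-20)
  expect_equal(q$p, 1)
  # LACEs (0, 1) with SEs (0.1, 0.1): Q = 50
  q2 <- cochran_q_test(make_strata(c(0, 1), c(0.1, 0.1)))
  expect_equal(q2$q, 50, tolerance = 1e-10)
  expect_equal(q2$p, pchisq(50, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(q2$p, 1.5e-12, tolerance = 0.05)
  st0 <- make_strata(c(0, 1), c(0, 0.1))
  expect_error(cochran_q_test(st0), "zero LACE")
})

test_that("the quadratic test is a weighted meta-regression on stratum exposure", {
  st <- make_strata(lace = rep(0.3, 3), lace_se = rep(0.1, 3))
  expect_equal(quadratic_test(st)$slope, 0, tolerance = 1e-12)
  # exactly linear LACE in mean exposure, equal weights: matches brute WLS
  st2 <- make_strata(lace = c(0.1, 0.2, 0.3), lace_se = rep(0.1, 3),
                     mean_exposure = c(5, 7, 9))
  qt <- quadratic_test(st2)
  brute <- coef(lm(lace ~ mean_exposure, data = st2,
                   weights = 1 / st2$lace_se^2))
  expect_equal(qt$slope, unname(brute[2]), tolerance = 1e-10)
  expect_equal(qt$slope, 0.05, tolerance = 1e-10)
  expect_error(quadratic_test(st2[1, ]), "at least 2")
})

test_that("non-linearity test power grows with curvature", {
  reject <- function(curv, nrep = 15) {
    mean(vapply(1:nrep, function(r) {
      co <- simulate_cohort(sim_config(
        n_samples = 30000, n_snps = 20, causal_shape = "quadratic_u",
        causal_params = list(curvature = curv), seed = 5000 + 100 * curv + r))
      grs <- build_grs(co$genotypes)
      ph <- co$phenotypes
      res <- iv_free_exposure(ph$exposure, grs)
      st <- lace_per_stratum(stratify_residuals(res, 3), grs, ph$exposure,
                             ph$hyperuricemia)
      quadratic_test(st)$p < 0.05
    }, logical(1)))
  }
  r0 <- reject(0)
  r2 <- reject(0.2)
  expect_lte(r0, 0.3)
  expect_gt(r2, r0)
  expect_gte(r2, 0.8)
})

test_that("within-stratum score-exposure slopes are compatible with the full sample", {
  co <- simulate_cohort(sim_config(n_samples = 30000, n_snps = 20, seed = 66))
  grs <- build_grs(co$genotypes)
  ph <- co$phenotypes
  res <- iv_free_exposure(ph$exposure, grs)
  st <- lace_per_stratum(stratify_residuals(res, 3), grs, ph$exposure,
                         ph$hyperuricemia, denominator = "stratum")
  full <- lace_per_stratum(stratify_residuals(res, 3), grs, ph$exposure,
                           ph$hyperuricemia, denominator = "full")
  z <- (st$beta_grs_exposure - full$beta_grs_exposure[1]) /
    sqrt(st$se_grs_exposure^2 + full$se_grs_exposure[1]^2)
  expect_true(all(abs(z) < 4))
})

test_that("the full non-linear wrapper returns a coherent result object", {
  co <- simulate_cohort(sim_config(n_samples = 8000, n_snps = 20,
                                   causal_shape = "quadratic_u",
                                   causal_params = list(curvature = 0.1),
                                   seed = 10))
  grs <- build_grs(co$genotypes)
  nl <- nonlinear_mr(grs, co$phenotypes$exposure,
                     co$phenotypes$hyperuricemia, k = 3,
                     min_stratum = 100, n_draws = 200, seed = 3)
  expect_s3_class(nl, "nonlinear_result")
  expect_equal(nrow(nl$strata), 3L)
  expect_true(all(diff(nl$strata$mean_exposure) > 0))
  expect_true(nl$cochran_q >= 0)
  expect_true(nl$quadratic_p >= 0 && nl$quadratic_p <= 1)
  ref_row <- nl$curve[nl$curve$hours == 7, ]
  expect_equal(ref_row$log_or, 0)
})
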