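# Shared fixtures, built in code at test time.

# Small summary-statistic table with an exactly common ratio b.
toy_summary_common_ratio <- function(b = 0.5, n_snps = 5) {
  bx <- seq(0.02, 0.1, length.out = n_snps)
  data.frame(snp_id = sprintf("s%d", seq_len(n_snps)),
             beta_exp = bx, se_exp = rep(0.005, n_snps),
             beta_out = b * bx, se_out = seq(0.01, 0.03,
                                             length.out = n_snps),
             eaf = rep(0.3, n_snps), stringsAsFactors = FALSE)
}

# Random (seeded) summary table under a linear causal slope, with
# normally distributed estimation noise.
sim_summary_linear <- function(n_snps, slope, gamma = 0.02,
                               se_exp = 0.002, se_out = 0.02, seed = 1) {
  set.seed(seed)
  g <- gamma * stats::runif(n_snps, 0.5, 1.5)
  data.frame(snp_id = sprintf("s%03d", seq_len(n_snps)),
             beta_exp = stats::rnorm(n_snps, g, se_exp),
             se_exp = rep(se_exp, n_snps),
             beta_out = stats::rnorm(n_snps, slope * g, se_out),
             se_out = rep(se_out, n_snps),
             eaf = rep(0.3, n_snps), stringsAsFactors = FALSE)
}

# Hand-built strata table for the non-linearity tests.
make_strata <- function(lace, lace_se, mean_exposure = seq_along(lace) + 4) {
  data.frame(index = seq_along(lace), n = rep(1000L, length(lace)),
             mean_exposure = mean_exposure,
             residual_lo = NA_real_, residual_hi = NA_real_,
             beta_grs_exposure = 1, se_grs_exposure = 0.01,
             beta_grs_outcome = lace, se_grs_outcome = lace_se,
             lace = lace, lace_se = lace_se, converged = TRUE)
}

# Quick default cohort used across tests.
quick_cohort <- function(n = 5000, shape = "linear",
                         params = list(slope = 0.1), seed = 7, ...) {
  simulate_cohort(sim_config(n_samples = n, n_snps = 20,
                             causal_shape = shape, causal_params = params,
                             seed = seed, ...))
}
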