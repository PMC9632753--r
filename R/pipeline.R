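#' Configuration for a full analysis run
#'
#' Collects the simulation settings, analysis toggles, QC thresholds and
#' multiple-testing family sizes for [run_pipeline()]. Every source of
#' randomness in the run derives from the single `seed`.
#'
#' @param simulation A [sim_config()] for the synthetic cohort (its seed
#'   is overridden by `seed`).
#' @param observational,linear,nonlinear,binary_exposure Stage toggles.
#' @param sex_filter `"all"` runs overall plus male and female subsets;
#'   `"male"`/`"female"` restricts to one sex.
#' @param thresholds A [qc_thresholds()] object.
#' @param m_populations Bonferroni family size for the linear MR estimates
#'   across populations (default 3: overall, males, females).
#' @param m_short_long Bonferroni family size for the short/long-sleep
#'   binary-exposure grid (default 6: two exposures by three populations).
#' @param k,reference_exposure,min_stratum Non-linear MR settings.
#' @param adjust Covariate names used in the MR regressions.
#' @param seed Master seed.
#' @return A `run_config` list.
#' @export
run_config <- function(simulation = sim_config(),
                       observational = TRUE, linear = TRUE,
                       nonlinear = TRUE, binary_exposure = FALSE,
                       sex_filter = c("all", "male", "female"),
                       thresholds = qc_thresholds(),
                       m_populations = 3, m_short_long = 6,
                       k = 3, reference_exposure = 7, min_stratum = 500,
                       adjust = c("age"),
                       seed = 1L) {
  sex_filter <- match.arg(sex_filter)
  if (!is_count(m_populations) || !is_count(m_short_long))
    stop2("multiple-testing family sizes must be positive integers")
  stopifnot(inherits(simulation, "sim_config"),
            inherits(thresholds, "qc_thresholds"))
  simulation$seed <- as.integer(seed)
  structure(list(simulation = simulation, observational = observational,
                 linear = linear, nonlinear = nonlinear,
                 binary_exposure = binary_exposure, sex_filter = sex_filter,
                 thresholds = thresholds, m_populations = m_populations,
                 m_short_long = m_short_long, k = k,
                 reference_exposure = reference_exposure,
                 min_stratum = min_stratum, adjust = adjust,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Recognised top-level keys mirror the [run_config()] arguments, with
#' `simulation:` and `thresholds:` sub-maps passed to [sim_config()] and
#' [qc_thresholds()].
#'
#' @param path Path to a YAML file.
#' @param seed Optional seed override.
#' @return A `run_config`.
#' @export
run_config_from_yaml <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  sim <- do.call(sim_config, y$simulation %||% list())
  thr <- do.call(qc_thresholds, y$thresholds %||% list())
  args <- y[setdiff(names(y), c("simulation", "thresholds"))]
  args$simulation <- sim
  args$thresholds <- thr
  if (!is.null(seed)) args$seed <- seed
  do.call(run_config, args)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes, as toggled: cohort simulation, instrument QC, risk-score
#' construction, the observational stage (category odds ratios and the
#' spline dose-response), linear MR (two-stage plus the summary-statistic
#' estimator suite with pleiotropy diagnostics), non-linear MR, and the
#' binary-exposure (short/long sleep) analyses with the
#' doubling-of-liability rescaling. Sex-specific runs are filtered repeats
#' of the same stages. Estimate p-values carry Bonferroni flags with the
#' configured family sizes.
#'
#' @param cfg A [run_config()].
#' @param out_dir Optional directory; when given, stage artifacts (TSVs)
#'   and the aggregated JSON report are written there.
#' @return A `run_report` list: `provenance`, `exclusions`, per-stage
#'   results, `warnings`.
#' @export
run_pipeline <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  warnings_log <- character(0)
  log_warn <- function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  run <- function(expr) withCallingHandlers(expr, warning = log_warn)

  report <- list(provenance = list(
    package_version = as.character(utils::packageVersion("slumr")),
    seed = cfg$seed,
    config = utils::capture.output(utils::str(cfg, give.attr = FALSE))))

  cohort <- run(simulate_cohort(cfg$simulation))
  ph <- cohort$phenotypes
  n_total <- nrow(ph)

  qc <- run(qc_filter(cohort$genotypes, cfg$thresholds))
  retained <- attr(qc, "retained")
  if (length(retained) == 0L) stop2("pipeline stage 'qc': no SNP survived")
  grs <- run(build_grs(cohort$genotypes, snps = retained))
  report$qc <- list(n_snps_input = nrow(qc), n_snps_retained = length(retained),
                    report = as.data.frame(qc))

  populations <- switch(cfg$sex_filter,
                        all = c("overall", "male", "female"),
                        male = "male", female = "female")
  pop_rows <- function(pop) if (pop == "overall") rep(TRUE, n_total)
    else ph$sex == pop

  cc <- stats::complete.cases(ph[, c("exposure", "hyperuricemia"), drop = FALSE])
  report$exclusions <- list(total = n_total, analyzed = sum(cc),
                            missing_phenotype = sum(!cc),
                            accounted = sum(cc) + sum(!cc) == n_total)

  if (isTRUE(cfg$observational)) {
    report$observational <- lapply(stats::setNames(populations, populations),
                                   function(pop) {
      rows <- pop_rows(pop) & cc
      sub <- ph[rows, , drop = FALSE]
      adj <- if (pop == "overall") c(cfg$adjust, "sex") else cfg$adjust
      ors <- run(fit_category_or(sub))
      ors_adj <- run(fit_category_or(sub, adjust = adj))
      curve <- run(rcs_dose_response(
        sub, spline_spec(reference_value = cfg$reference_exposure)))
      list(crude_or = ors, adjusted_or = ors_adj,
           spline_curve = as.data.frame(curve))
    })
  }

  if (isTRUE(cfg$linear)) {
    lin <- lapply(stats::setNames(populations, populations), function(pop) {
      rows <- pop_rows(pop) & cc
      sub <- ph[rows, , drop = FALSE]
      g <- grs[rows]
      adj <- sub[, intersect(cfg$adjust, names(sub)), drop = FALSE]
      two_stage <- run(mr_two_stage(g, sub$exposure, sub$hyperuricemia,
                                    covariates = adj))
      geno_sub <- structure(list(
        dosages = cohort$genotypes$dosages[rows, retained, drop = FALSE],
        meta = cohort$genotypes$meta[
          match(retained, cohort$genotypes$meta$snp_id), , drop = FALSE]),
        class = "genotype_matrix")
      ss <- run(compute_summary_stats(geno_sub, sub, "binary"))
      ivw <- run(mr_ivw(ss))
      egger <- run(mr_egger(ss))
      wm <- run(mr_weighted_median(ss, seed = child_seed(cfg$seed, 11L)))
      presso <- run(mr_presso(ss, seed = child_seed(cfg$seed, 12L)))
      list(two_stage = two_stage, ivw = ivw, egger = egger,
           weighted_median = wm, presso = presso, summary_stats = ss)
    })
    ps <- vapply(lin, function(l) l$two_stage$p_value, numeric(1))
    flags <- bonferroni_flag(ps, cfg$m_populations)
    for (i in seq_along(lin)) lin[[i]]$two_stage_significant <- flags[i]
    report$linear <- lin
    report$linear_bonferroni_threshold <- attr(flags, "threshold")
  }

  if (isTRUE(cfg$nonlinear)) {
    report$nonlinear <- lapply(stats::setNames(populations, populations),
                               function(pop) {
      rows <- pop_rows(pop) & cc
      sub <- ph[rows, , drop = FALSE]
      run(nonlinear_mr(grs[rows], sub$exposure, sub$hyperuricemia,
                       k = cfg$k,
                       reference_exposure = cfg$reference_exposure,
                       min_stratum = min(cfg$min_stratum,
                                         floor(sum(rows) / cfg$k)),
                       n_draws = 500,
                       seed = child_seed(cfg$seed, 13L)))
    })
  }

  if (isTRUE(cfg$binary_exposure)) {
    specs <- list(short = list(n_snps = 26L, stream = 21L),
                  long = list(n_snps = 7L, stream = 22L))
    be <- list()
    ps <- numeric(0)
    for (trait in names(specs)) {
      sim <- cfg$simulation
      sim$n_snps <- specs[[trait]]$n_snps
      sim$exposure_family <- "binary_liability"
      sim$exposure_prevalence <- if (trait == "short") 0.24 else 0.08
      sim$seed <- child_seed(cfg$seed, specs[[trait]]$stream)
      co <- run(simulate_cohort(sim))
      g2 <- run(build_grs(co$genotypes))
      for (pop in populations) {
        rows <- if (pop == "overall") rep(TRUE, nrow(co$phenotypes))
          else co$phenotypes$sex == pop
        est <- run(mr_two_stage(g2[rows], co$phenotypes$exposure[rows],
                                co$phenotypes$hyperuricemia[rows]))
        est <- rescale_binary_exposure(est)
        be[[paste(trait, pop, sep = "_")]] <- est
        ps <- c(ps, est$p_value)
      }
    }
    flags <- bonferroni_flag(ps, cfg$m_short_long)
    for (i in seq_along(be)) be[[i]]$significant <- flags[i]
    report$binary_exposure <- be
    report$binary_exposure_bonferroni_threshold <- attr(flags, "threshold")
  }

  report$warnings <- warnings_log
  class(report) <- "run_report"

  if (!is.null(out_dir)) write_run_report(report, cohort, out_dir)
  report
}

# Persist pipeline artifacts: TSVs per stage plus an aggregated JSON report.
write_run_report <- function(report, cohort, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes(cohort$genotypes, file.path(out_dir, "dosages.tsv"),
                  file.path(out_dir, "snp_meta.tsv"))
  write_phenotypes(cohort$phenotypes, file.path(out_dir, "phenotypes.tsv"))
  utils::write.table(report$qc$report, file.path(out_dir, "qc_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  json <- jsonlite::toJSON(strip_for_json(unclass(report)),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           force = TRUE)
  writeLines(json, file.path(out_dir, "report.json"))
  invisible(out_dir)
}

# Drop bulky components (curves, raw summary tables are written separately).
strip_for_json <- function(x) {
  if (inherits(x, "nonlinear_result"))
    x <- list(strata = x$strata, cochran_q = x$cochran_q,
              cochran_q_p = x$cochran_q_p, quadratic_p = x$quadratic_p)
  if (is.list(x)) {
    x <- x[setdiff(names(x), c("spline_curve", "summary_stats", "curve"))]
    x <- lapply(x, strip_for_json)
  }
  x
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run report\n")
  cat(sprintf("  seed %d; %d/%d records analyzed (%d excluded)\n",
              x$provenance$seed, x$exclusions$analyzed, x$exclusions$total,
              x$exclusions$missing_phenotype))
  cat(sprintf("  QC: %d of %d SNPs retained\n",
              x$qc$n_snps_retained, x$qc$n_snps_input))
  if (!is.null(x$linear))
    for (pop in names(x$linear)) {
      e <- x$linear[[pop]]$two_stage
      cat(sprintf("  linear MR [%s]: OR %.3f (%.3f-%.3f), p = %.3g, n = %s\n",
                  pop, exp(e$beta), exp(e$ci_low), exp(e$ci_high),
                  e$p_value, format(e$n_snps)))
    }
  if (!is.null(x$nonlinear))
    for (pop in names(x$nonlinear)) {
      nl <- x$nonlinear[[pop]]
      cat(sprintf("  non-linear MR [%s]: Q p = %.3g, quadratic p = %.3g\n",
                  pop, nl$cochran_q_p, nl$quadratic_p))
    }
  if (length(x$warnings))
    cat(sprintf("  %d warning(s) logged\n", length(x$warnings)))
  invisible(x)
}
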