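#' Quality-control thresholds for genetic instruments
#'
#' Defaults mirror the conventional genomic QC used for sleep-duration
#' instruments: INFO score at least 0.9, minor allele frequency at least
#' 0.01, Hardy-Weinberg p-value at least 1e-5, and pairwise linkage
#' disequilibrium r-squared at most 0.1.
#'
#' @param info_min Minimum imputation-quality (INFO) score.
#' @param maf_min Minimum minor allele frequency.
#' @param hwe_p_min Minimum Hardy-Weinberg equilibrium p-value.
#' @param ld_r2_max Maximum pairwise squared correlation among retained
#'   SNPs.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(info_min = 0.9, maf_min = 0.01,
                          hwe_p_min = 1e-5, ld_r2_max = 0.1) {
  vals <- c(info_min = info_min, maf_min = maf_min,
            hwe_p_min = hwe_p_min, ld_r2_max = ld_r2_max)
  if (any(vals <= 0 | vals >= 1))
    stop2("all thresholds must lie in (0, 1)")
  structure(as.list(vals), class = "qc_thresholds")
}

#' Hardy-Weinberg equilibrium goodness-of-fit test
#'
#' One-degree-of-freedom chi-square test of observed genotype counts
#' against the expectations implied by the sample allele frequency.
#'
#' @param genotype_counts Integer vector of length 3: counts of the three
#'   genotypes (reference homozygote, heterozygote, alternate homozygote).
#' @return The p-value. Monomorphic input returns `p = 1` with a warning.
#' @export
hwe_test <- function(genotype_counts) {
  if (length(genotype_counts) != 3L || any(genotype_counts < 0))
    stop2("genotype_counts must be three non-negative counts")
  n <- sum(genotype_counts)
  if (n == 0) stop2("empty genotype table")
  p <- (2 * genotype_counts[3] + genotype_counts[2]) / (2 * n)
  if (p == 0 || p == 1) {
    warn2("monomorphic SNP: Hardy-Weinberg test undefined, returning p = 1")
    return(1)
  }
  expected <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  chi2 <- sum((genotype_counts - expected)^2 / expected)
  stats::pchisq(chi2, df = 1, lower.tail = FALSE)
}

# Genotype counts from a dosage vector; imputed (non-integer) dosages are
# rounded to best-guess genotypes with a warning.
dosage_counts <- function(d) {
  if (any(d != round(d))) {
    warn2("non-integer dosages rounded to best-guess genotypes for the HWE test")
    d <- round(d)
  }
  c(sum(d == 0), sum(d == 1), sum(d == 2))
}

#' Greedy LD pruning by GWAS p-value priority
#'
#' Visits SNPs in ascending discovery p-value (ties broken by input order)
#' and retains a SNP only if its squared Pearson correlation with every
#' already-retained SNP is at most `r2_max` — the standard clumping
#' convention.
#'
#' @param g A `genotype_matrix`, or a plain dosage matrix.
#' @param r2_max Maximum allowed pairwise r-squared.
#' @param priority Optional numeric vector (e.g. GWAS p-values) defining
#'   the visit order (ascending); defaults to the `gwas_p` metadata, or
#'   input order when absent.
#' @return Character vector of retained SNP ids, with a `dropped`
#'   attribute naming each excluded SNP and the reason.
#' @export
ld_prune <- function(g, r2_max = 0.1, priority = NULL) {
  if (inherits(g, "genotype_matrix")) {
    dos <- g$dosages
    if (is.null(priority)) priority <- g$meta$gwas_p
  } else {
    dos <- as.matrix(g)
  }
  p <- ncol(dos)
  if (p < 1) stop2("need at least one SNP")
  ids <- colnames(dos) %||% paste0("snp_", seq_len(p))
  if (is.null(priority)) priority <- seq_len(p)
  ord <- order(priority)  # stable: ties keep input order
  retained <- integer(0)
  dropped <- character(0)
  dropped_reason <- character(0)
  for (j in ord) {
    v <- stats::var(dos[, j])
    if (v == 0) {
      dropped <- c(dropped, ids[j])
      dropped_reason <- c(dropped_reason, "constant column (correlation undefined)")
      next
    }
    if (length(retained)) {
      r2 <- suppressWarnings(
        stats::cor(dos[, j], dos[, retained, drop = FALSE]))^2
      if (any(r2 > r2_max, na.rm = TRUE)) {
        dropped <- c(dropped, ids[j])
        dropped_reason <- c(dropped_reason,
                            sprintf("LD r2 %.3f with %s",
                                    max(r2, na.rm = TRUE),
                                    ids[retained[which.max(r2)]]))
        next
      }
    }
    retained <- c(retained, j)
  }
  out <- ids[sort(retained)]
  attr(out, "dropped") <- stats::setNames(dropped_reason, dropped)
  out
}

#' Instrument quality control
#'
#' Applies the INFO, minor-allele-frequency and Hardy-Weinberg filters to
#' every SNP, then LD-prunes the survivors so all retained pairwise
#' r-squared values stay at or below the threshold. Every decision is
#' recorded; an empty survivor set is a valid outcome.
#'
#' @param g A `genotype_matrix`.
#' @param thresholds A [qc_thresholds()] object.
#' @return A `qc_report` data.frame with one row per SNP: `snp_id`,
#'   `pass`, `fail_reasons` (comma-separated, drawn from INFO/MAF/HWE/LD),
#'   `maf`, `hwe_p`, `info`, `max_r2_retained`. The retained SNP ids are
#'   attached as attribute `retained`.
#' @export
qc_filter <- function(g, thresholds = qc_thresholds()) {
  stopifnot(inherits(g, "genotype_matrix"))
  t <- thresholds
  meta <- g$meta
  p <- nrow(meta)
  maf <- pmin(meta$eaf, 1 - meta$eaf)
  hwe_p <- vapply(seq_len(p), function(j)
    suppressWarnings(hwe_test(dosage_counts(g$dosages[, j]))), numeric(1))
  reasons <- vector("list", p)
  for (j in seq_len(p)) {
    r <- character(0)
    if (meta$info[j] < t$info_min) r <- c(r, "INFO")
    if (maf[j] < t$maf_min) r <- c(r, "MAF")
    if (hwe_p[j] < t$hwe_p_min) r <- c(r, "HWE")
    reasons[[j]] <- r
  }
  survivors <- which(lengths(reasons) == 0L)
  max_r2 <- rep(NA_real_, p)
  if (length(survivors)) {
    sub <- structure(list(
      dosages = g$dosages[, survivors, drop = FALSE],
      meta = meta[survivors, , drop = FALSE]), class = "genotype_matrix")
    kept_ids <- ld_prune(sub, r2_max = t$ld_r2_max)
    for (j in survivors) {
      id <- meta$snp_id[j]
      if (!(id %in% kept_ids)) reasons[[j]] <- c(reasons[[j]], "LD")
      others <- setdiff(kept_ids, id)
      if (length(others))
        max_r2[j] <- max(suppressWarnings(
          stats::cor(g$dosages[, j],
                     g$dosages[, others, drop = FALSE]))^2, na.rm = TRUE)
    }
  }
  pass <- lengths(reasons) == 0L
  out <- data.frame(snp_id = meta$snp_id, pass = pass,
                    fail_reasons = vapply(reasons, paste, character(1),
                                          collapse = ","),
                    maf = maf, hwe_p = hwe_p, info = meta$info,
                    max_r2_retained = max_r2,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("qc_report", "data.frame")
  attr(out, "retained") <- meta$snp_id[pass]
  out
}

#' Unweighted genetic risk score (allele count)
#'
#' Sums, per individual, the dosages of the exposure-increasing allele
#' across instrument SNPs. Where the increasing allele is the SNP's other
#' (non-effect) allele the dosage is re-oriented as `2 - d` before
#' summation. The score is unweighted by design.
#'
#' @param g A `genotype_matrix`.
#' @param increasing_allele Character vector, one allele label per SNP
#'   (defaults to each SNP's effect allele, i.e. no flips).
#' @param snps Optional subset of SNP ids to use (e.g. the QC survivors).
#' @return Numeric vector of scores (one per sample), each in
#'   `[0, 2 * n_snps_used]`; `n_snps_used` is attached as an attribute.
#' @export
build_grs <- function(g, increasing_allele = NULL, snps = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  meta <- g$meta
  dos <- g$dosages
  if (!is.null(snps)) {
    keep <- match(snps, meta$snp_id)
    if (anyNA(keep)) stop2("unknown SNP id: %s",
                           paste(snps[is.na(keep)], collapse = ", "))
    meta <- meta[keep, , drop = FALSE]
    dos <- dos[, keep, drop = FALSE]
  }
  p <- nrow(meta)
  if (is.null(increasing_allele)) increasing_allele <- meta$effect_allele
  if (length(increasing_allele) != p)
    stop2("need one increasing-allele label per SNP (%d != %d)",
          length(increasing_allele), p)
  flip <- increasing_allele == meta$other_allele
  keep_as_is <- increasing_allele == meta$effect_allele
  bad <- !(flip | keep_as_is)
  if (any(bad))
    stop2("increasing allele '%s' matches neither allele of SNP %s",
          increasing_allele[which(bad)[1]], meta$snp_id[which(bad)[1]])
  oriented <- dos
  if (any(flip)) oriented[, flip] <- 2 - oriented[, flip]
  score <- rowSums(oriented)
  attr(score, "n_snps_used") <- p
  score
}

#' Instrument strength: partial R-squared and F-statistic
#'
#' Partial variance in the exposure explained by the genetic risk score
#' given the covariates, and the corresponding single-degree-of-freedom
#' F-statistic `F = (n - k - 1) r2 / (1 - r2)` where `k` counts the score
#' plus covariate terms. F above 10 is the conventional bar for
#' instruments that are not weak.
#'
#' @param grs Genetic risk score vector.
#' @param exposure Exposure vector.
#' @param covariates Optional covariate data.frame/matrix.
#' @return List `F_stat`, `r2`, `n`, `weak` (logical, `F < 10`).
#' @export
instrument_strength <- function(grs, exposure, covariates = NULL) {
  n <- length(exposure)
  stopifnot(length(grs) == n)
  covs <- covariate_matrix(covariates, n)
  X0 <- cbind(rep(1, n), covs)
  X1 <- cbind(X0, grs = grs)
  q0 <- qr(X0); q1 <- qr(X1)
  if (q1$rank < ncol(X1)) stop2("collinear regressors (rank-deficient fit)")
  rss0 <- sum(qr.resid(q0, exposure)^2)
  rss1 <- sum(qr.resid(q1, exposure)^2)
  r2 <- (rss0 - rss1) / rss0
  k <- ncol(X1) - 1L  # non-intercept regressors in the full model
  if (rss1 <= .Machine$double.eps * rss0)
    stop2("exposure is an exact function of the score (r2 = 1): F undefined")
  f <- (n - k - 1) * r2 / (1 - r2)
  list(F_stat = f, r2 = r2, n = n, weak = f < 10)
}
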