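# Plain-text (TSV) readers and writers for the package's data containers.

#' Write / read a genotype matrix as TSV
#'
#' The dosage matrix is written samples x SNPs with a header row of SNP
#' ids, and the per-variant metadata (snp_id, effect_allele, other_allele,
#' eaf, info, gwas_p) as a companion TSV.
#'
#' @param g A `genotype_matrix`.
#' @param dosage_file,meta_file Output (or input) paths.
#' @return `write_genotypes` returns the paths invisibly; `read_genotypes`
#'   returns a `genotype_matrix`.
#' @export
write_genotypes <- function(g, dosage_file, meta_file) {
  stopifnot(inherits(g, "genotype_matrix"))
  utils::write.table(g$dosages, dosage_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(g$meta, meta_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(dosage_file, meta_file))
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(dosage_file, meta_file) {
  dos <- as.matrix(utils::read.delim(dosage_file, check.names = FALSE))
  meta <- utils::read.delim(meta_file, stringsAsFactors = FALSE)
  if (!identical(colnames(dos), meta$snp_id))
    stop2("dosage columns and metadata rows disagree")
  structure(list(dosages = dos, meta = meta), class = "genotype_matrix")
}

#' Write / read a phenotype table as TSV
#'
#' @param ph Phenotype data.frame.
#' @param file Path.
#' @export
write_phenotypes <- function(ph, file) {
  utils::write.table(ph, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(file) {
  ph <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (!is.null(ph$sex)) ph$sex <- factor(ph$sex, levels = c("male", "female"))
  ph
}

#' Write / read per-SNP summary statistics as TSV
#'
#' Columns: snp_id, beta_exp, se_exp, beta_out, se_out, eaf.
#'
#' @param s A `snp_summary` data.frame.
#' @param file Path.
#' @export
write_snp_summary <- function(s, file) {
  utils::write.table(s, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_snp_summary
#' @export
read_snp_summary <- function(file) {
  s <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("snp_id", "beta_exp", "se_exp", "beta_out", "se_out")
  miss <- setdiff(need, names(s))
  if (length(miss)) stop2("summary file lacks columns: %s",
                          paste(miss, collapse = ", "))
  class(s) <- c("snp_summary", "data.frame")
  s
}
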