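#' Read and write the package's tab-delimited interchange formats
#'
#' Cohort tables are plain TSV, one row per participant, with the fixed
#' header `study_id, id, dosage_<rsid> x4, adiponectin, met_*, age, sex,
#' center, pc*, smoking, bmi, high_risk`. Instrument sets and summary-level
#' SNP-metabolite tables use the GWAS-summary-style header
#' `rsid, effect_allele, other_allele, eaf, beta, se, n [, metabolite]`.
#'
#' @param x Table to write.
#' @param path File path.
#' @return `write_*` return `x` invisibly; `read_*` return a tibble (cohorts
#'   gain class `cohort_tbl`, instruments `instrument_set`).
#' @name adipomet-io
NULL

#' @rdname adipomet-io
#' @export
write_cohort_tsv <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path)
  invisible(x)
}

#' @rdname adipomet-io
#' @export
read_cohort_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  class(out) <- c("cohort_tbl", class(out))
  out
}

#' @rdname adipomet-io
#' @export
write_instruments_tsv <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path)
  invisible(x)
}

#' @rdname adipomet-io
#' @export
read_instruments_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("rsid", "effect_allele", "other_allele", "eaf", "beta", "se", "n")
  miss <- setdiff(need, names(out))
  if (length(miss) > 0) {
    stop("instrument file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  class(out) <- c("instrument_set", class(out))
  out
}
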