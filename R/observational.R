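#' Standardize adiponectin to the exposure scale
#'
#' Natural log, then centre and scale to unit SD within the study, giving the
#' "per 1 SD of log adiponectin" exposure scale on which all effect sizes are
#' expressed.
#'
#' @param adiponectin Positive concentrations.
#' @return Numeric vector with mean 0 and SD 1.
#' @export
standardize_exposure <- function(adiponectin) {
  bad <- which(!is.na(adiponectin) & adiponectin <= 0)
  if (length(bad) > 0) {
    stop("adiponectin must be strictly positive; offending record(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  l <- log(adiponectin)
  s <- stats::sd(l, na.rm = TRUE)
  if (is.na(s) || s == 0) {
    stop("adiponectin has zero variance; cannot standardize", call. = FALSE)
  }
  (l - mean(l, na.rm = TRUE)) / s
}

#' Stage-1 multivariable regression for one study
#'
#' Ordinary least-squares slope (with intercept) of each transformed
#' metabolite on standardized log adiponectin, the first stage of the
#' two-stage individual-participant meta-analysis. SEs come from the usual
#' residual-variance formula and p-values from a two-sided normal test.
#' Metabolites with fewer than `min_n` usable participants are suppressed
#' with a warning naming them.
#'
#' @param panel A `preprocessed_panel` (or any data frame of `met_*`
#'   columns), rows aligned with `exposure`.
#' @param exposure Standardized log adiponectin, as from
#'   [standardize_exposure()], in the same participant order as `panel`.
#' @param study_id Study label for the output; defaults to the panel's
#'   `study_id` column when present.
#' @param min_n Minimum usable n per metabolite (default 10).
#' @return A tibble of association estimates: `study_id`, `metabolite`,
#'   `arm = "multivariable"`, `beta`, `se`, `n`, `p`.
#' @export
fit_study <- function(panel, exposure, study_id = NULL, min_n = 10) {
  mets <- metabolite_cols(panel)
  if (length(mets) == 0) stop("no `met_*` columns in panel", call. = FALSE)
  if (length(exposure) != nrow(panel)) {
    stop("`exposure` must align with `panel` rows", call. = FALSE)
  }
  # canonical participant order, so estimates are invariant to permutation
  if ("id" %in% names(panel)) {
    ord <- if ("study_id" %in% names(panel)) {
      order(panel$study_id, panel$id)
    } else {
      order(panel$id)
    }
    panel <- panel[ord, , drop = FALSE]
    exposure <- exposure[ord]
  }
  if (is.null(study_id)) {
    study_id <- if ("study_id" %in% names(panel)) panel$study_id[1] else "study"
  }
  est <- .ols_slopes(exposure, panel[mets], mets)
  low <- !is.na(est$n) & est$n < min_n | is.na(est$beta)
  if (any(low)) {
    warning("suppressing ", sum(low), " metabolite(s) with n < ", min_n,
            " usable participants: ",
            paste(utils::head(est$metabolite[low], 5), collapse = ", "),
            call. = FALSE)
    est <- est[!low, , drop = FALSE]
  }
  tibble::tibble(
    study_id = study_id,
    metabolite = est$metabolite,
    arm = "multivariable",
    beta = est$beta,
    se = est$se,
    n = as.integer(est$n),
    p = .two_sided_p(est$beta, est$se)
  )
}
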