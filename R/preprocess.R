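#' Residualize metabolite columns on study covariates
#'
#' Per-study covariate adjustment: each metabolite is regressed by ordinary
#' least squares (with intercept) on the listed covariates and replaced by its
#' residuals. Participants missing the metabolite or any covariate are
#' excluded for that metabolite only (their residual is `NA`), so the usable
#' n can differ across metabolites. Categorical covariates (e.g. recruitment
#' centre) are expanded to indicator columns. Covariates with zero variance
#' are dropped with a warning; a rank-deficient design is an error naming the
#' collinear columns.
#'
#' @param cohort A data frame with `met_*` columns and the covariates.
#' @param covariates Character vector of covariate column names; empty means
#'   intercept-only adjustment (centering).
#' @return A tibble with `study_id`/`id` (when present) and the residualized
#'   `met_*` columns, rows in canonical participant order.
#' @export
residualize <- function(cohort, covariates = character()) {
  cohort <- .sort_by_id(cohort)
  mets <- metabolite_cols(cohort)
  if (length(mets) == 0) stop("no `met_*` columns found", call. = FALSE)
  missing_cov <- setdiff(covariates, names(cohort))
  if (length(missing_cov) > 0) {
    stop("covariates not present in cohort: ",
         paste(missing_cov, collapse = ", "), call. = FALSE)
  }

  keep <- character()
  for (cv in covariates) {
    v <- cohort[[cv]]
    if (length(unique(v[!is.na(v)])) < 2) {
      warning("dropping zero-variance covariate `", cv, "`", call. = FALSE)
    } else {
      keep <- c(keep, cv)
    }
  }

  if (length(keep) == 0) {
    X <- matrix(1, nrow(cohort), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    fm <- stats::reformulate(keep)
    mf <- stats::model.frame(fm, data = cohort, na.action = stats::na.pass)
    X <- stats::model.matrix(fm, mf)
  }
  cc_X <- stats::complete.cases(X)
  qrX <- qr(X[cc_X, , drop = FALSE])
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient covariate design; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  Y <- as.matrix(cohort[mets])
  res <- matrix(NA_real_, nrow(cohort), length(mets),
                dimnames = list(NULL, mets))
  if (!anyNA(Y) && all(cc_X)) {
    res[] <- qr.resid(qrX, Y)
  } else {
    for (j in seq_along(mets)) {
      ok <- cc_X & !is.na(Y[, j])
      if (sum(ok) > ncol(X)) {
        res[ok, j] <- qr.resid(qr(X[ok, , drop = FALSE]), Y[ok, j])
      }
    }
  }

  idc <- intersect(c("study_id", "id"), names(cohort))
  dplyr::bind_cols(tibble::as_tibble(cohort[idc]),
                   tibble::as_tibble(as.data.frame(res)))
}

#' Inverse rank-based normal transformation
#'
#' Maps the value with rank `r` among `n` non-missing observations to
#' `qnorm((r - c) / (n - 2c + 1))` with the Blom offset `c = 3/8`; ties get
#' the mean of their ranks and missing values stay missing. The output is
#' rank-preserving and has the quantiles of a standard normal.
#'
#' @param x Numeric vector with at least 3 non-missing values.
#' @param offset Rank offset `c` (default `3/8`, Blom).
#' @return Numeric vector of the same length as `x`.
#' @export
inverse_normal_transform <- function(x, offset = 3 / 8) {
  ok <- !is.na(x)
  n <- sum(ok)
  if (n < 3) stop("need at least 3 non-missing values", call. = FALSE)
  if (length(unique(x[ok])) == 1) {
    stop("all values identical; rank transformation undefined", call. = FALSE)
  }
  out <- rep(NA_real_, length(x))
  r <- rank(x[ok], ties.method = "average")
  out[ok] <- stats::qnorm((r - offset) / (n - 2 * offset + 1))
  out
}

#' Residualize and inverse-normal transform a cohort's metabolite panel
#'
#' The two-step analysis-scale preparation applied within each study (and,
#' for stratified runs, within each analysis stratum): covariate
#' residualization via [residualize()], then [inverse_normal_transform()] per
#' metabolite.
#'
#' @inheritParams residualize
#' @param offset Rank offset passed to [inverse_normal_transform()].
#' @return A tibble of class `preprocessed_panel` with id columns and
#'   transformed `met_*` columns; per-metabolite usable counts are attached
#'   as attribute `"n_used"`.
#' @export
preprocess_cohort <- function(cohort, covariates = c("age", "sex"),
                              offset = 3 / 8) {
  panel <- residualize(cohort, covariates)
  mets <- metabolite_cols(panel)
  for (m in mets) panel[[m]] <- inverse_normal_transform(panel[[m]], offset)
  attr(panel, "n_used") <- vapply(panel[mets], function(v) sum(!is.na(v)), 0L)
  class(panel) <- c("preprocessed_panel", class(panel))
  panel
}

#' Effective number of independent tests from a correlation matrix
#'
#' The number of principal components needed to explain strictly more than
#' the stated fraction of total variance: eigenvalues of the correlation
#' matrix are clipped at zero (guarding against tiny negative values from a
#' singular matrix) and `k` is the smallest count whose cumulative share
#' exceeds `var_threshold`.
#'
#' @param R Correlation matrix.
#' @param var_threshold Fraction of variance to exceed (default 0.95, read
#'   strictly).
#' @return Integer `k`.
#' @export
n_independent_tests <- function(R, var_threshold = 0.95) {
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  ev[ev < 0] <- 0
  cum <- cumsum(ev) / sum(ev)
  as.integer(which(cum > var_threshold)[1])
}

#' Multiple-testing plan from the effective number of independent tests
#'
#' Estimates the number of independent tests among correlated metabolic
#' measures as the number of principal components explaining over
#' `var_threshold` of total variance (complete-case participants, PCA on the
#' correlation matrix), then divides the family-wise alpha by that count
#' (Bonferroni). The per-test alpha is stored at full precision; `print()`
#' shows it to 2 significant figures.
#'
#' @param panel A data frame with transformed `met_*` columns (or a bare
#'   numeric matrix of measures).
#' @param alpha_family Family-wise error rate (default 0.05).
#' @param var_threshold Variance fraction for the component count.
#' @return An object of class `testing_plan`: a list with `n_measures`,
#'   `n_independent_tests`, `alpha_family`, `alpha_per_test`.
#' @export
effective_tests <- function(panel, alpha_family = 0.05, var_threshold = 0.95) {
  M <- if (is.matrix(panel)) panel else as.matrix(panel[metabolite_cols(panel)])
  if (ncol(M) < 1) stop("no metabolite columns found", call. = FALSE)
  M <- M[stats::complete.cases(M), , drop = FALSE]
  if (nrow(M) <= ncol(M)) {
    stop("need more complete-case participants (", nrow(M),
         ") than measures (", ncol(M), ")", call. = FALSE)
  }
  if (ncol(M) == 1) {
    k <- 1L
  } else {
    constant <- apply(M, 2, stats::sd) == 0
    if (any(constant)) {
      stop("constant measures cannot enter the correlation matrix: ",
           paste(colnames(M)[constant], collapse = ", "), call. = FALSE)
    }
    k <- n_independent_tests(stats::cor(M), var_threshold)
  }
  .new_testing_plan(ncol(M), k, alpha_family)
}

.new_testing_plan <- function(n_measures, k, alpha_family) {
  structure(list(
    n_measures = as.integer(n_measures),
    n_independent_tests = as.integer(k),
    alpha_family = alpha_family,
    alpha_per_test = alpha_family / k
  ), class = "testing_plan")
}

#' @export
print.testing_plan <- function(x, ...) {
  cat("<testing_plan> ", x$n_measures, " measures, ",
      x$n_independent_tests, " independent tests; per-test alpha = ",
      signif(x$alpha_per_test, 2), " (family ", x$alpha_family, ")\n",
      sep = "")
  invisible(x)
}

#' Shared multiple-testing plan across reference studies
#'
#' When several reference panels are designated (the studies with the widest
#' metabolite coverage), the component count is computed per panel and the
#' maximum is taken -- the most conservative choice consistent with reporting
#' a single shared threshold.
#'
#' @param panels A list of panels acceptable to [effective_tests()].
#' @inheritParams effective_tests
#' @return A `testing_plan`.
#' @export
shared_testing_plan <- function(panels, alpha_family = 0.05,
                                var_threshold = 0.95) {
  stopifnot(length(panels) >= 1)
  plans <- purrr::map(panels, effective_tests,
                      alpha_family = alpha_family,
                      var_threshold = var_threshold)
  k <- max(purrr::map_int(plans, "n_independent_tests"))
  n <- max(purrr::map_int(plans, "n_measures"))
  .new_testing_plan(n, k, alpha_family)
}
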