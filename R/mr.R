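.palindromic <- function(a1, a2) {
  paste0(a1, a2) %in% c("AT", "TA", "CG", "GC")
}

#' Harmonize SNP-outcome associations to the instrument's effect alleles
#'
#' Aligns a table of SNP-outcome summary statistics to an instrument set so
#' Wald ratios divide effects coded on the same allele: outcome betas coded
#' on the instrument's other allele are sign-flipped (and their EAF
#' complemented, when present); strand-ambiguous palindromic SNPs (A/T or
#' C/G) whose instrument EAF falls in the ambiguity window are dropped with a
#' message, as are SNPs missing from either side or with irreconcilable
#' alleles.
#'
#' @param instruments An `instrument_set` (columns `rsid`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`).
#' @param outcome_assocs SNP-outcome associations with columns `rsid`,
#'   `effect_allele`, `beta_y`, `se_y` (plus `other_allele`, `eaf`,
#'   `metabolite`, `study_id`, `n` when available).
#' @param palindromic_window EAF window `[lo, hi]` within which palindromic
#'   SNPs are considered unresolvable (default `c(0.42, 0.58)`).
#' @return A tibble: the harmonized outcome rows joined with the instrument's
#'   `beta_x = beta`, `se_x = se`, `effect_allele` recoded to the
#'   instrument's. Dropped rsids and reasons are attached as attribute
#'   `"dropped"`.
#' @export
harmonize <- function(instruments, outcome_assocs,
                      palindromic_window = c(0.42, 0.58)) {
  ins <- tibble::as_tibble(instruments)
  out <- tibble::as_tibble(outcome_assocs)
  dropped <- tibble::tibble(rsid = character(), reason = character())

  missing <- setdiff(unique(out$rsid), ins$rsid)
  if (length(missing) > 0) {
    dropped <- dplyr::bind_rows(dropped, tibble::tibble(
      rsid = missing, reason = "absent from instrument set"))
    out <- out[out$rsid %in% ins$rsid, , drop = FALSE]
  }

  pal <- ins$rsid[.palindromic(ins$effect_allele, ins$other_allele) &
                    ins$eaf >= palindromic_window[1] &
                    ins$eaf <= palindromic_window[2]]
  if (length(pal) > 0) {
    message("dropping strand-ambiguous palindromic SNP(s) with EAF in [",
            palindromic_window[1], ", ", palindromic_window[2], "]: ",
            paste(pal, collapse = ", "))
    dropped <- dplyr::bind_rows(dropped, tibble::tibble(
      rsid = pal, reason = "palindromic with ambiguous EAF"))
    out <- out[!out$rsid %in% pal, , drop = FALSE]
  }

  key <- ins[, c("rsid", "effect_allele", "other_allele", "beta", "se")]
  names(key) <- c("rsid", "ea_ins", "oa_ins", "beta_x", "se_x")
  m <- dplyr::left_join(out, key, by = "rsid")

  aligned <- m$effect_allele == m$ea_ins
  flipped <- m$effect_allele == m$oa_ins
  bad <- !aligned & !flipped
  if (any(bad)) {
    bad_rs <- unique(m$rsid[bad])
    dropped <- dplyr::bind_rows(dropped, tibble::tibble(
      rsid = bad_rs, reason = "allele mismatch"))
    message("dropping SNP(s) with irreconcilable alleles: ",
            paste(bad_rs, collapse = ", "))
    m <- m[!bad, , drop = FALSE]
    aligned <- aligned[!bad]; flipped <- flipped[!bad]
  }
  m$beta_y[flipped] <- -m$beta_y[flipped]
  if ("eaf" %in% names(m)) m$eaf[flipped] <- 1 - m$eaf[flipped]
  m$effect_allele <- m$ea_ins
  if ("other_allele" %in% names(m)) m$other_allele <- m$oa_ins
  m$ea_ins <- NULL; m$oa_ins <- NULL

  if (nrow(m) == 0) stop("no usable instruments after harmonization",
                         call. = FALSE)
  attr(m, "dropped") <- dropped
  m
}

#' Per-study SNP-outcome regressions
#'
#' The genetic-association half of the two-sample design: for each instrument
#' SNP and each transformed metabolite, the OLS slope (with intercept) of the
#' metabolite on allele dosage under the additive genetic model, with SE and
#' usable n. SNPs that are monomorphic in the study are excluded with a
#' warning.
#'
#' @param cohort A `cohort_tbl` for one study (provides `dosage_*` columns).
#' @param panel The matching `preprocessed_panel`.
#' @param snps Instrument annotation (for the effect-allele labels); defaults
#'   to the annotation attached to `cohort` by [simulate_cohorts()].
#' @return A tibble with `rsid`, `metabolite`, `study_id`, `beta_y`, `se_y`,
#'   `n`, `effect_allele`.
#' @export
snp_outcome_regressions <- function(cohort, panel,
                                    snps = attr(cohort, "snps")) {
  cohort <- .sort_by_id(cohort)
  panel <- .sort_by_id(panel)
  if ("id" %in% names(cohort) && "id" %in% names(panel) &&
      !identical(cohort$id, panel$id)) {
    stop("cohort and panel participant ids do not align", call. = FALSE)
  }
  dcols <- dosage_cols(cohort)
  if (length(dcols) == 0) stop("no `dosage_*` columns in cohort", call. = FALSE)
  rsids <- sub("^dosage_", "", dcols)
  mets <- metabolite_cols(panel)
  study <- if ("study_id" %in% names(cohort)) cohort$study_id[1] else "study"
  ea <- if (!is.null(snps)) {
    snps$effect_allele[match(rsids, snps$rsid)]
  } else rep(NA_character_, length(rsids))

  res <- purrr::map(seq_along(dcols), function(j) {
    g <- cohort[[dcols[j]]]
    if (stats::var(g, na.rm = TRUE) == 0) {
      warning("SNP ", rsids[j], " is monomorphic in ", study,
              "; excluded", call. = FALSE)
      return(NULL)
    }
    est <- .ols_slopes(g, panel[mets], mets)
    tibble::tibble(
      rsid = rsids[j], metabolite = est$metabolite, study_id = study,
      beta_y = est$beta, se_y = est$se, n = as.integer(est$n),
      effect_allele = ea[j]
    )
  })
  purrr::list_rbind(purrr::compact(res))
}

#' Wald ratio for a single SNP
#'
#' The per-SNP instrumental-variable estimate: SNP-outcome effect divided by
#' SNP-exposure effect. The default SE is the first-order delta-method form
#' `se_y / |beta_x|`, which ignores the (second-sample) uncertainty in
#' `beta_x`; `second_order = TRUE` adds the `beta_y^2 se_x^2 / beta_x^4`
#' term. SNPs with first-stage `|beta_x| / se_x < 2` trigger a
#' weak-instrument warning and are flagged in the output.
#'
#' @param beta_x,se_x SNP-exposure effect and SE (vectorized).
#' @param beta_y,se_y SNP-outcome effect and SE.
#' @param second_order Use the second-order delta-method SE?
#' @return A tibble with `ratio`, `se`, `weak_instrument`.
#' @export
wald_ratio <- function(beta_x, se_x, beta_y, se_y, second_order = FALSE) {
  if (any(beta_x == 0)) stop("`beta_x` must be nonzero", call. = FALSE)
  weak <- abs(beta_x) / se_x < 2
  if (any(weak)) {
    warning("weak instrument: |beta_x|/se_x < 2 for ", sum(weak), " SNP(s)",
            call. = FALSE)
  }
  se <- if (second_order) {
    sqrt(se_y^2 / beta_x^2 + beta_y^2 * se_x^2 / beta_x^4)
  } else {
    se_y / abs(beta_x)
  }
  tibble::tibble(ratio = beta_y / beta_x, se = se, weak_instrument = weak)
}

#' Inverse-variance-weighted combination of Wald ratios
#'
#' Fixed-effect IVW estimate across the instrument SNPs:
#' `beta = sum(beta_x * beta_y / se_y^2) / sum(beta_x^2 / se_y^2)` with
#' `se = sqrt(1 / sum(beta_x^2 / se_y^2))` -- algebraically the
#' inverse-variance-weighted average of per-SNP Wald ratios with weights
#' `(beta_x / se_y)^2`, and equally the weighted least-squares slope of
#' `beta_y` on `beta_x` through the origin with weights `1 / se_y^2`. With a
#' single SNP it reduces exactly to [wald_ratio()].
#'
#' @param harmonized A data frame with columns `beta_x`, `beta_y`, `se_y`
#'   (one row per SNP), as produced by [harmonize()].
#' @return A one-row tibble with `beta`, `se`, `p` (two-sided normal) and
#'   `n_snps_used`.
#' @export
ivw_combine <- function(harmonized) {
  h <- harmonized[stats::complete.cases(
    harmonized[, c("beta_x", "beta_y", "se_y")]), , drop = FALSE]
  if (nrow(h) == 0) stop("no SNPs to combine", call. = FALSE)
  w <- h$beta_x^2 / h$se_y^2
  beta <- sum(h$beta_x * h$beta_y / h$se_y^2) / sum(w)
  se <- sqrt(1 / sum(w))
  tibble::tibble(beta = beta, se = se, p = .two_sided_p(beta, se),
                 n_snps_used = nrow(h))
}

#' Two-sample MR estimates for one study, all metabolites
#'
#' Harmonizes the study's SNP-outcome regressions against the external
#' instrument set and applies fixed-effect IVW per metabolite (random-effects
#' pooling happens later, across studies).
#'
#' @param instruments An `instrument_set`.
#' @param outcome_assocs Output of [snp_outcome_regressions()] or
#'   [export_summary_study()] for one study.
#' @inheritParams harmonize
#' @return A tibble of MR association estimates: `study_id`, `metabolite`,
#'   `arm = "mr"`, `beta`, `se`, `n`, `p`, `n_snps_used`.
#' @export
mr_study <- function(instruments, outcome_assocs,
                     palindromic_window = c(0.42, 0.58)) {
  h <- harmonize(instruments, outcome_assocs, palindromic_window)
  study <- if ("study_id" %in% names(h)) h$study_id[1] else "study"
  h |>
    dplyr::group_by(.data$metabolite) |>
    dplyr::group_modify(function(d, key) {
      est <- ivw_combine(d)
      est$n <- as.integer(max(d$n))
      est
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(study_id = study, arm = "mr") |>
    dplyr::select("study_id", "metabolite", "arm", "beta", "se", "n", "p",
                  "n_snps_used")
}

#' Instrument-confounder balance checks
#'
#' Tests each instrument SNP against the classical confounders: linear
#' regression of continuous confounders on allele dosage, logistic regression
#' (log-odds per allele) of binary confounders. A valid instrument should
#' show only chance associations here. Confounders with a single observed
#' level are skipped with a warning.
#'
#' @param cohort A `cohort_tbl` for one study.
#' @param confounders Confounder columns to test (default sex, age, first
#'   ancestry PC, current smoking, BMI).
#' @return A tibble with `study_id`, `rsid`, `confounder`, `type`
#'   (`"linear"`/`"logistic"`), `estimate`, `se`, `p`.
#' @export
confounder_balance <- function(cohort,
                               confounders = c("sex", "age", "pc1",
                                               "smoking", "bmi")) {
  missing_cf <- setdiff(confounders, names(cohort))
  if (length(missing_cf) > 0) {
    stop("confounders not present: ", paste(missing_cf, collapse = ", "),
         call. = FALSE)
  }
  dcols <- dosage_cols(cohort)
  rsids <- sub("^dosage_", "", dcols)
  study <- if ("study_id" %in% names(cohort)) cohort$study_id[1] else "study"

  rows <- list()
  for (cf in confounders) {
    v <- cohort[[cf]]
    lv <- unique(v[!is.na(v)])
    if (length(lv) < 2) {
      warning("confounder `", cf, "` has a single level; skipped",
              call. = FALSE)
      next
    }
    binary <- length(lv) == 2
    for (j in seq_along(dcols)) {
      g <- cohort[[dcols[j]]]
      if (binary) {
        y <- as.integer(v == max(lv))
        fit <- stats::glm(y ~ g, family = stats::binomial())
        cf_est <- summary(fit)$coefficients["g", ]
        rows[[length(rows) + 1]] <- tibble::tibble(
          study_id = study, rsid = rsids[j], confounder = cf,
          type = "logistic", estimate = cf_est[["Estimate"]],
          se = cf_est[["Std. Error"]], p = cf_est[["Pr(>|z|)"]])
      } else {
        est <- .ols_slopes(g, matrix(v, ncol = 1), cf)
        rows[[length(rows) + 1]] <- tibble::tibble(
          study_id = study, rsid = rsids[j], confounder = cf,
          type = "linear", estimate = est$beta, se = est$se,
          p = .two_sided_p(est$beta, est$se))
      }
    }
  }
  purrr::list_rbind(rows)
}
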