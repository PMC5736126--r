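#' Z-test comparison of the multivariable and MR arms per metabolite
#'
#' Contrasts the two pooled estimates for each metabolite with the unpooled
#' independent-samples Z statistic
#' `z = (beta_mv - beta_mr) / sqrt(se_mv^2 + se_mr^2)` and a two-sided normal
#' p-value, and flags each arm's significance against the multiple-testing
#' plan's per-test alpha. Metabolites present in only one arm are emitted
#' with the available side and a missing `z`/`p_diff`.
#'
#' @param mv,mr Pooled estimates (from [pool_estimates()]) for the
#'   multivariable and MR arm respectively; columns `metabolite`, `beta`,
#'   `se`, `p`.
#' @param plan A `testing_plan` (for the Bonferroni flags).
#' @return A tibble with one row per metabolite: `metabolite`, `beta_mv`,
#'   `se_mv`, `p_mv`, `beta_mr`, `se_mr`, `p_mr`, `z`, `p_diff`, `sig_mv`,
#'   `sig_mr`.
#' @export
z_compare <- function(mv, mr, plan) {
  stopifnot(inherits(plan, "testing_plan"))
  a <- plan$alpha_per_test
  mv2 <- dplyr::select(tibble::as_tibble(mv), "metabolite",
                       beta_mv = "beta", se_mv = "se", p_mv = "p")
  mr2 <- dplyr::select(tibble::as_tibble(mr), "metabolite",
                       beta_mr = "beta", se_mr = "se", p_mr = "p")
  dplyr::full_join(mv2, mr2, by = "metabolite") |>
    dplyr::mutate(
      z = (.data$beta_mv - .data$beta_mr) /
        sqrt(.data$se_mv^2 + .data$se_mr^2),
      p_diff = .two_sided_p(.data$z, 1),
      sig_mv = !is.na(.data$p_mv) & .data$p_mv < a,
      sig_mr = !is.na(.data$p_mr) & .data$p_mr < a
    ) |>
    dplyr::arrange(.data$metabolite)
}

#' Profile-level summary of the two arms
#'
#' Counts, per arm, the metabolites associated at the nominal level
#' (p < 0.05) and after Bonferroni correction (p < the plan's per-test
#' alpha), and computes the Pearson correlation of the multivariable and MR
#' point estimates across metabolites with both arms present (unweighted, as
#' in a scatter of estimates). Fewer than 2 complete pairs leaves the
#' correlation missing with a warning.
#'
#' @param records Output of [z_compare()].
#' @param plan The `testing_plan` used for the Bonferroni counts.
#' @return A one-row tibble: `n_metabolites`, `n_nominal_mv`,
#'   `n_bonferroni_mv`, `n_nominal_mr`, `n_bonferroni_mr`, `pearson_r`,
#'   `alpha_per_test`.
#' @export
profile_summary <- function(records, plan) {
  stopifnot(inherits(plan, "testing_plan"))
  a <- plan$alpha_per_test
  complete <- !is.na(records$beta_mv) & !is.na(records$beta_mr)
  r <- if (sum(complete) >= 2) {
    stats::cor(records$beta_mv[complete], records$beta_mr[complete])
  } else {
    warning("fewer than 2 metabolites with both arms; correlation not ",
            "computed", call. = FALSE)
    NA_real_
  }
  tibble::tibble(
    n_metabolites = nrow(records),
    n_nominal_mv = sum(records$p_mv < 0.05, na.rm = TRUE),
    n_bonferroni_mv = sum(records$p_mv < a, na.rm = TRUE),
    n_nominal_mr = sum(records$p_mr < 0.05, na.rm = TRUE),
    n_bonferroni_mr = sum(records$p_mr < a, na.rm = TRUE),
    pearson_r = r,
    alpha_per_test = a
  )
}
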