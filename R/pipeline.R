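#' Run the full two-arm adiponectin-metabolome analysis
#'
#' End-to-end pipeline over a set of individual-level cohorts (and optional
#' summary-level studies):
#' 1. preprocess each cohort (covariate residualization + inverse-normal
#'    transform);
#' 2. multivariable arm: per-study regression of each metabolite on
#'    standardized log adiponectin (studies lacking adiponectin are skipped
#'    for this arm);
#' 3. MR arm: per-study SNP-outcome regressions harmonized against the
#'    external instrument set, combined by fixed-effect IVW within study;
#' 4. DerSimonian-Laird random-effects pooling of each arm across studies;
#' 5. multiple-testing plan from the reference studies' panels (max
#'    component count across them);
#' 6. per-metabolite Z comparison and profile summary.
#'
#' @param cohorts A `cohort_tbl` (stacked studies, as from
#'   [simulate_cohorts()]) or a list of single-study tables.
#' @param instruments An `instrument_set` of external SNP-exposure effects;
#'   when `NULL` and `cohorts` carries a simulation config, one is exported
#'   from an independent mega-sample via [export_instrument_summary()].
#' @param covariates Covariates for the residualization stage.
#' @param reference_studies Study ids whose panels define the
#'   multiple-testing plan; defaults to the first two studies (the widest
#'   panels in this generator, where all studies share the full panel).
#' @param summary_studies Optional list of summary-level SNP-metabolite
#'   tables (as from [export_summary_study()]) contributing to the MR arm
#'   only.
#' @param alpha_family Family-wise alpha for the plan.
#' @return An object of class `adipo_profile`: a list with `plan`,
#'   `estimates` (stage-1, both arms), `pooled`, `comparison`, `summary`,
#'   and `instruments`. Supports [tidy()], [glance()], [autoplot()].
#' @export
run_profile <- function(cohorts, instruments = NULL,
                        covariates = c("age", "sex"),
                        reference_studies = NULL,
                        summary_studies = list(),
                        alpha_family = 0.05) {
  if (is.data.frame(cohorts)) {
    snps <- attr(cohorts, "snps")
    cfg <- attr(cohorts, "config")
    cohort_list <- split(tibble::as_tibble(cohorts), cohorts$study_id)
    cohort_list <- purrr::map(cohort_list, function(d) {
      attr(d, "snps") <- snps
      d
    })
  } else {
    cohort_list <- cohorts
    cfg <- attr(cohort_list[[1]], "config")
  }
  if (is.null(instruments)) {
    if (is.null(cfg)) {
      stop("`instruments` must be supplied for cohorts without an attached ",
           "simulation config", call. = FALSE)
    }
    instruments <- export_instrument_summary(cfg)
  }

  panels <- purrr::map(cohort_list, preprocess_cohort, covariates = covariates)

  # multivariable arm: only studies measuring adiponectin
  mv <- purrr::imap(cohort_list, function(cohort, sid) {
    if (!"adiponectin" %in% names(cohort) ||
        all(is.na(cohort$adiponectin))) return(NULL)
    cohort <- .sort_by_id(cohort)
    fit_study(panels[[sid]], standardize_exposure(cohort$adiponectin),
              study_id = sid)
  })
  mv <- purrr::list_rbind(purrr::compact(unname(mv)))

  # MR arm: individual-level studies plus any summary-level contributions
  mr_inputs <- c(
    purrr::map(names(cohort_list), function(sid) {
      snp_outcome_regressions(cohort_list[[sid]], panels[[sid]])
    }),
    summary_studies
  )
  mr <- purrr::list_rbind(purrr::map(mr_inputs, function(assoc) {
    mr_study(instruments, assoc)
  }))

  ref <- reference_studies %||% utils::head(names(cohort_list), 2)
  plan <- shared_testing_plan(panels[ref], alpha_family = alpha_family)

  estimates <- dplyr::bind_rows(mv, mr[, intersect(names(mr), names(mv))])
  pooled <- pool_estimates(estimates)
  comparison <- z_compare(
    dplyr::filter(pooled, .data$arm == "multivariable"),
    dplyr::filter(pooled, .data$arm == "mr"),
    plan
  )
  structure(list(
    plan = plan,
    estimates = estimates,
    pooled = pooled,
    comparison = comparison,
    summary = profile_summary(comparison, plan),
    instruments = instruments
  ), class = "adipo_profile")
}

#' @export
print.adipo_profile <- function(x, ...) {
  s <- x$summary
  cat("<adipo_profile> ", s$n_metabolites, " metabolites, ",
      length(unique(x$estimates$study_id)), " studies\n", sep = "")
  print(x$plan)
  cat("  multivariable: ", s$n_nominal_mv, " nominal / ",
      s$n_bonferroni_mv, " Bonferroni-significant\n", sep = "")
  cat("  MR:            ", s$n_nominal_mr, " nominal / ",
      s$n_bonferroni_mr, " Bonferroni-significant\n", sep = "")
  cat("  correlation of estimates (MV vs MR): r = ",
      signif(s$pearson_r, 2), "\n", sep = "")
  invisible(x)
}

#' @rdname run_profile
#' @param x An `adipo_profile`.
#' @param ... Unused.
#' @method tidy adipo_profile
#' @export
tidy.adipo_profile <- function(x, ...) x$comparison

#' @rdname run_profile
#' @method glance adipo_profile
#' @export
glance.adipo_profile <- function(x, ...) x$summary

#' Scatter of multivariable versus MR estimates
#'
#' The profile-level comparison picture: each point is a metabolite, placed
#' at its pooled multivariable estimate (x) and pooled MR estimate (y), with
#' the identity line that causal agreement would follow. A wide horizontal
#' spread with points hugging `y = 0` is the signature of confounded
#' observational associations without causal support.
#'
#' @param object An `adipo_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot adipo_profile
#' @export
autoplot.adipo_profile <- function(object, ...) {
  d <- dplyr::filter(object$comparison,
                     !is.na(.data$beta_mv), !is.na(.data$beta_mr))
  r <- object$summary$pearson_r
  ggplot2::ggplot(d, ggplot2::aes(x = .data$beta_mv, y = .data$beta_mr)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted", colour = "grey50") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = "Multivariable estimate (SD metabolite per SD log adiponectin)",
      y = "Mendelian randomization estimate",
      title = "Observational vs causal metabolite associations",
      subtitle = paste0("Pearson r = ", signif(r, 2))
    ) +
    ggplot2::theme_minimal()
}

#' Forest-style plot of pooled estimates
#'
#' Pooled effect and 95% CI per metabolite, one panel per arm, with
#' heterogeneity class mapped to point shape.
#'
#' @param pooled A pooled-estimate tibble (from [pool_estimates()]) or an
#'   `adipo_profile`.
#' @param metabolites Optional subset of metabolites to display.
#' @return A ggplot object.
#' @export
plot_forest <- function(pooled, metabolites = NULL) {
  if (inherits(pooled, "adipo_profile")) pooled <- pooled$pooled
  d <- pooled
  if (!is.null(metabolites)) {
    d <- dplyr::filter(d, .data$metabolite %in% metabolites)
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$beta, y = .data$metabolite,
                                  shape = .data$het_class)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$beta - 1.96 * .data$se,
                   xmax = .data$beta + 1.96 * .data$se),
      height = 0.2, colour = "grey30") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~arm) +
    ggplot2::labs(x = "Pooled estimate (95% CI)", y = NULL,
                  shape = "Heterogeneity") +
    ggplot2::theme_minimal()
}
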