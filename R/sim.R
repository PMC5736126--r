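#' Simulate individual-level multi-study cohort data
#'
#' Draws, for each study, Hardy-Weinberg genotypes at the four instrument
#' SNPs, a latent confounder, standardized log adiponectin
#' `A = sum_j gamma_j G*_j + delta * C + e`, a block-correlated metabolite
#' panel `M_i = theta_i * A + lambda_is * C + u_i`, and inert demographic
#' covariates (age, sex, centre, ancestry PCs, smoking, BMI, high-risk flag).
#' BMI tracks the latent confounder, so it behaves like the adiposity marker
#' it stands for; the other covariates carry no effects by default so that
#' covariate adjustment is testably neutral. Between-study heterogeneity
#' enters as a per-study normal perturbation of the confounder loadings
#' `lambda_i` with SD `study_heterogeneity_sd`.
#'
#' @param config A [sim_config()].
#' @return A tibble of class `cohort_tbl`, one row per participant across all
#'   studies, with columns `study_id`, `id`, `dosage_<rsid>` (x4),
#'   `adiponectin`, `met_001..met_NNN`, `age`, `sex`, `center`, `pc1`, `pc2`,
#'   `smoking`, `bmi`, `high_risk`. The generating `sim_config` is attached as
#'   attribute `"config"` and the instrument annotation as `"snps"`.
#' @export
simulate_cohorts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  snps   <- config$snps
  p      <- snps$eaf
  truth  <- sim_truth(config)
  gamma  <- truth$gamma_std
  delta  <- config$delta
  theta  <- config$theta
  lambda <- config$lambda
  nv     <- config$noise_var
  rho    <- config$within_block_corr
  blocks <- rep(seq_along(config$block_sizes), config$block_sizes)
  n_met  <- config$n_metabolites
  met_names <- sprintf("met_%03d", seq_len(n_met))

  one_study <- function(s) {
    n <- config$n_per_study
    lambda_s <- lambda + stats::rnorm(n_met, 0, config$study_heterogeneity_sd)
    G <- vapply(p, function(pp) stats::rbinom(n, 2L, pp), integer(n))
    Gstar <- sweep(sweep(G, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), "/")
    C <- stats::rnorm(n)
    A <- drop(Gstar %*% gamma) + delta * C +
      stats::rnorm(n, 0, sqrt(config$resid_var_adiponectin))
    Z <- matrix(stats::rnorm(n * length(config$block_sizes)), n)
    E <- matrix(stats::rnorm(n * n_met), n)
    U <- sweep(sqrt(rho) * Z[, blocks, drop = FALSE] + sqrt(1 - rho) * E,
               2, sqrt(nv), "*")
    M <- outer(A, theta) + outer(C, lambda_s) + U
    colnames(M) <- met_names

    age <- round(stats::rnorm(n, 55, 8), 1)
    bmi <- 26 + 3.5 * (0.6 * C + sqrt(1 - 0.36) * stats::rnorm(n)) +
      config$confounder_snp_effect * G[, 1]
    prior_cvd <- stats::rbinom(n, 1L, 0.08)

    dos <- tibble::as_tibble(as.data.frame(G))
    names(dos) <- paste0("dosage_", snps$rsid)

    dplyr::bind_cols(
      tibble::tibble(
        study_id = sprintf("study_%02d", s),
        id = sprintf("s%02d_%06d", s, seq_len(n))
      ),
      dos,
      tibble::tibble(
        adiponectin = exp(config$adiponectin_meanlog +
                            config$adiponectin_sdlog * A)
      ),
      tibble::as_tibble(as.data.frame(M)),
      tibble::tibble(
        age = age,
        sex = stats::rbinom(n, 1L, 0.5),
        center = sample(c("centre_a", "centre_b"), n, replace = TRUE),
        pc1 = stats::rnorm(n),
        pc2 = stats::rnorm(n),
        smoking = stats::rbinom(n, 1L, 0.25),
        bmi = bmi,
        high_risk = as.integer(prior_cvd == 1L | age > 65)
      )
    )
  }

  out <- purrr::list_rbind(purrr::map(seq_len(config$n_studies), one_study))
  attr(out, "config") <- config
  attr(out, "snps") <- snps
  class(out) <- c("cohort_tbl", class(out))
  out
}

#' Names of metabolite columns in a cohort or panel table
#' @param x A data frame.
#' @return Character vector of `met_*` column names, in order.
#' @export
metabolite_cols <- function(x) {
  grep("^met_[0-9]+$", names(x), value = TRUE)
}

#' Names of SNP dosage columns in a cohort table
#' @param x A data frame.
#' @return Character vector of `dosage_*` column names, in order.
#' @export
dosage_cols <- function(x) {
  grep("^dosage_", names(x), value = TRUE)
}

#' Export instrument summary statistics from an independent mega-sample
#'
#' Emulates downloading SNP-to-adiponectin association summary statistics
#' from a large external GWAS consortium: a single independent sample of
#' `mega_n` participants is drawn from the same generative model (a stream of
#' randomness disjoint from [simulate_cohorts()], preserving the two-sample
#' property), log adiponectin is standardized within the sample, and each
#' SNP's per-allele effect is estimated by simple linear regression on dosage.
#'
#' @param config A [sim_config()].
#' @param mega_n Sample size of the external consortium (default 30000,
#'   the order of magnitude of adiponectin GWAS discovery samples); must be
#'   at least 1000.
#' @return A tibble of class `instrument_set` with columns `rsid`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `n` -- `beta` in
#'   standardized log-adiponectin units per effect allele.
#' @export
export_instrument_summary <- function(config, mega_n = 30000) {
  stopifnot(inherits(config, "sim_config"))
  if (mega_n < 1000) stop("`mega_n` must be >= 1000", call. = FALSE)
  # disjoint seed stream: the external sample never shares randomness with
  # the cohorts, which is what makes the design two-sample
  set.seed(config$seed + 1000003L)
  p <- config$snps$eaf
  gamma <- sim_truth(config)$gamma_std
  n <- as.integer(mega_n)
  G <- vapply(p, function(pp) stats::rbinom(n, 2L, pp), integer(n))
  Gstar <- sweep(sweep(G, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), "/")
  C <- stats::rnorm(n)
  A <- drop(Gstar %*% gamma) + config$delta * C +
    stats::rnorm(n, 0, sqrt(config$resid_var_adiponectin))
  log_adipo <- config$adiponectin_meanlog + config$adiponectin_sdlog * A
  y <- as.numeric(scale(log_adipo))

  fits <- purrr::map(seq_len(4L), function(j) {
    f <- .ols_slopes(G[, j], matrix(y, ncol = 1), "adiponectin")
    tibble::tibble(beta = f$beta, se = f$se)
  })
  out <- dplyr::bind_cols(
    config$snps[, c("rsid", "effect_allele", "other_allele")],
    tibble::tibble(
      eaf = colMeans(G) / 2,
      beta = purrr::map_dbl(fits, "beta"),
      se = purrr::map_dbl(fits, "se"),
      n = n
    )
  )
  class(out) <- c("instrument_set", class(out))
  out
}

#' Export a summary-level SNP-metabolite association study
#'
#' Emulates a consortium that contributes only summary statistics: the
#' cohort's metabolites are covariate-adjusted and inverse-normal transformed
#' exactly as in the individual-level analysis, then each (SNP, metabolite)
#' pair is summarized by a single-SNP regression. The output is identical,
#' row for row, to running [snp_outcome_regressions()] on the preprocessed
#' cohort, so summary-level and individual-level studies enter the MR arm
#' through the same estimator.
#'
#' @param cohort A `cohort_tbl` (one study).
#' @param covariates Covariate columns to residualize on before the rank
#'   transformation (default `c("age", "sex")`).
#' @return A tibble with columns `rsid`, `metabolite`, `study_id`, `beta_y`,
#'   `se_y`, `n`, `effect_allele`: 4 x n_metabolites rows.
#' @export
export_summary_study <- function(cohort, covariates = c("age", "sex")) {
  if (nrow(cohort) < 10) {
    stop("refusing to summarize a cohort with fewer than 10 participants",
         call. = FALSE)
  }
  panel <- preprocess_cohort(cohort, covariates = covariates)
  snp_outcome_regressions(cohort, panel)
}
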