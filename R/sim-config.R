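#' Default cis-ADIPOQ instrument panel
#'
#' The four independent SNPs in the vicinity of the *ADIPOQ* locus that
#' instrument circulating adiponectin, with effect/other alleles and the
#' default effect-allele frequencies used by the simulator. The frequency for
#' rs17366568 is a configurable placeholder (no published value is wired in);
#' the other three sit inside the ranges reported for European cohort studies.
#'
#' @return A tibble with columns `rsid`, `effect_allele`, `other_allele`, `eaf`.
#' @export
default_snp_panel <- function() {
  tibble::tibble(
    rsid          = c("rs6810075", "rs16861209", "rs17366568", "rs3774261"),
    effect_allele = c("T", "A", "A", "G"),
    other_allele  = c("C", "C", "G", "A"),
    eaf           = c(0.67, 0.10, 0.85, 0.39)
  )
}

# even-ish partition of n metabolites into n_blocks correlated blocks
.default_blocks <- function(n, n_blocks = 7L) {
  n_blocks <- min(n_blocks, n)
  sizes <- rep(n %/% n_blocks, n_blocks)
  extra <- n %% n_blocks
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  sizes
}

#' Configure the multi-study synthetic data generator
#'
#' Defines the generative model for a set of cohort studies: Hardy-Weinberg
#' genotypes at four cis instruments, standardized log adiponectin `A` built
#' from the instruments, a latent standard-normal adiposity/insulin-resistance
#' confounder `C`, and a block-correlated metabolite panel
#' `M_i = theta_i * A + lambda_i * C + noise`. All variables are generated on
#' the standardized scale, so variance components of each variable must sum
#' to at most 1.
#'
#' Under this model the population multivariable (observational) slope of a
#' metabolite on standardized log adiponectin is `theta_i + delta * lambda_i`
#' (confounded when `lambda_i != 0`), while the causal estimand targeted by
#' Mendelian randomization is `theta_i` alone. Both truths are exposed via
#' [sim_truth()] so tests can compare each arm against its own estimand.
#'
#' @param n_studies Number of cohort studies.
#' @param n_per_study Participants per study.
#' @param n_metabolites Width of the metabolite panel (default 74).
#' @param block_sizes Integer partition of `n_metabolites` into correlated
#'   blocks; defaults to seven near-equal blocks, emulating lipoprotein
#'   subclass groupings of an NMR panel.
#' @param within_block_corr Correlation of the block-shared noise component,
#'   in `[0, 1)`. The implied metabolite-metabolite correlation within a block
#'   is `lambda_i * lambda_j + rho * sqrt(v_i * v_j)` at `theta = 0`.
#' @param eaf Effect-allele frequency for each of the 4 SNPs, each in (0, 1).
#' @param snp_r2_adiponectin Fraction of adiponectin variance jointly explained
#'   by the instruments (default 0.04); split equally across SNPs on the
#'   standardized-dosage scale.
#' @param confounder_effect_on_adiponectin Standardized slope `delta` of the
#'   latent confounder on log adiponectin.
#' @param confounder_effect_on_metabolites Standardized slope(s) `lambda_i`;
#'   scalar recycled or a length-`n_metabolites` vector.
#' @param causal_effect True causal effect(s) `theta_i` of standardized log
#'   adiponectin on each standardized metabolite (default all 0).
#' @param study_heterogeneity_sd Between-study SD of an additive perturbation
#'   of each `lambda_i`, the mechanism generating nonzero I-squared.
#' @param confounder_snp_effect Slope of the first SNP's dosage on BMI
#'   (kg/m^2 per effect allele); default 0, i.e. instruments are independent
#'   of classical confounders. Nonzero values deliberately violate the
#'   instrumental-variable assumption for power checks of the balance test.
#' @param adiponectin_meanlog,adiponectin_sdlog Location and scale mapping the
#'   standardized latent `A` to a reported concentration
#'   `exp(meanlog + sdlog * A)` (default median about 8 ug/mL).
#' @param snps Instrument annotation table as from [default_snp_panel()];
#'   `eaf` overrides its frequency column.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_cohorts()], [export_instrument_summary()]
#' @export
sim_config <- function(n_studies = 5,
                       n_per_study = 2000,
                       n_metabolites = 74,
                       block_sizes = NULL,
                       within_block_corr = 0.85,
                       eaf = default_snp_panel()$eaf,
                       snp_r2_adiponectin = 0.04,
                       confounder_effect_on_adiponectin = 0.5,
                       confounder_effect_on_metabolites = 0.6,
                       causal_effect = 0,
                       study_heterogeneity_sd = 0.05,
                       confounder_snp_effect = 0,
                       adiponectin_meanlog = log(8),
                       adiponectin_sdlog = 0.55,
                       snps = default_snp_panel(),
                       seed = 1L) {
  if (is.null(block_sizes)) block_sizes <- .default_blocks(n_metabolites)
  if (sum(block_sizes) != n_metabolites) {
    stop("`block_sizes` must sum to `n_metabolites` (got ", sum(block_sizes),
         " vs ", n_metabolites, ")", call. = FALSE)
  }
  if (any(block_sizes < 1)) stop("`block_sizes` must be positive", call. = FALSE)
  if (within_block_corr < 0 || within_block_corr >= 1) {
    stop("`within_block_corr` must be in [0, 1)", call. = FALSE)
  }
  stopifnot(nrow(snps) == 4L, !anyDuplicated(snps$rsid),
            all(snps$effect_allele != snps$other_allele))
  if (length(eaf) != 4L || any(eaf <= 0) || any(eaf >= 1)) {
    stop("`eaf` must be 4 frequencies in (0, 1)", call. = FALSE)
  }
  snps$eaf <- eaf
  if (snp_r2_adiponectin < 0 || snp_r2_adiponectin >= 1) {
    stop("`snp_r2_adiponectin` must be in [0, 1)", call. = FALSE)
  }

  delta  <- confounder_effect_on_adiponectin
  theta  <- rep_len(causal_effect, n_metabolites)
  lambda <- rep_len(confounder_effect_on_metabolites, n_metabolites)

  # variance budgets on the standardized scale
  resid_a <- 1 - snp_r2_adiponectin - delta^2
  if (resid_a <= 0) {
    stop("variance budget exceeded for adiponectin: snp_r2 + delta^2 = ",
         signif(snp_r2_adiponectin + delta^2, 4), " >= 1", call. = FALSE)
  }
  noise_var <- 1 - (theta^2 + lambda^2 + 2 * theta * lambda * delta)
  if (any(noise_var <= 0)) {
    bad <- which(noise_var <= 0)[1]
    stop("variance budget exceeded for met_", sprintf("%03d", bad),
         ": theta^2 + lambda^2 + 2*theta*lambda*delta >= 1", call. = FALSE)
  }

  structure(list(
    n_studies = as.integer(n_studies),
    n_per_study = as.integer(n_per_study),
    n_metabolites = as.integer(n_metabolites),
    block_sizes = as.integer(block_sizes),
    within_block_corr = within_block_corr,
    snps = snps,
    snp_r2_adiponectin = snp_r2_adiponectin,
    delta = delta,
    theta = theta,
    lambda = lambda,
    noise_var = noise_var,
    resid_var_adiponectin = resid_a,
    study_heterogeneity_sd = study_heterogeneity_sd,
    confounder_snp_effect = confounder_snp_effect,
    adiponectin_meanlog = adiponectin_meanlog,
    adiponectin_sdlog = adiponectin_sdlog,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_studies, " studies x ", x$n_per_study,
      " participants, ", x$n_metabolites, " metabolites\n", sep = "")
  cat("  SNP R2 on adiponectin: ", x$snp_r2_adiponectin,
      "; confounder slope delta = ", x$delta, "\n", sep = "")
  cat("  causal effect theta in [", min(x$theta), ", ", max(x$theta),
      "]; lambda in [", min(x$lambda), ", ", max(x$lambda), "]\n", sep = "")
  invisible(x)
}

#' True generative quantities behind a simulated dataset
#'
#' @param x A `cohort_tbl` from [simulate_cohorts()] or a `sim_config`.
#' @return A list with per-SNP effects on the standardized (`gamma_std`) and
#'   per-allele (`gamma_per_allele`) scale, the confounder slopes `delta` and
#'   `lambda`, the causal effects `theta`, and the population confounded
#'   multivariable slope `theta + delta * lambda` per metabolite.
#' @export
sim_truth <- function(x) {
  cfg <- if (inherits(x, "sim_config")) x else attr(x, "config")
  if (is.null(cfg)) stop("no simulation config attached to `x`", call. = FALSE)
  gamma_std <- rep(sqrt(cfg$snp_r2_adiponectin / 4), 4)
  sd_dosage <- sqrt(2 * cfg$snps$eaf * (1 - cfg$snps$eaf))
  list(
    gamma_std = gamma_std,
    gamma_per_allele = gamma_std / sd_dosage,
    delta = cfg$delta,
    lambda = cfg$lambda,
    theta = cfg$theta,
    confounded_slope = cfg$theta + cfg$delta * cfg$lambda,
    noise_var = cfg$noise_var
  )
}
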