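---
title: "Two-arm profiling of adiponectin and the metabolome: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-arm profiling of adiponectin and the metabolome: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adipomet)
```

## The question and the two arms

Multivariable regression of metabolic measures on circulating adiponectin
estimates an association that mixes any causal effect of adiponectin with
the influence of shared upstream factors — most plausibly adiposity and
insulin resistance, both of which suppress adiponectin and derange the
metabolome. Mendelian randomization (MR) replaces the measured exposure
with genetic variants at the *ADIPOQ* locus: because alleles are assigned
at meiosis, the variant-metabolite association is protected from classical
confounding and reverse causation, and under the instrumental-variable
assumptions its ratio to the variant-adiponectin association estimates the
causal effect. `adipomet` runs both arms on the same studies and asks
whether they agree.

The observational arm is a two-stage individual-participant meta-analysis:
per-study ordinary least squares of each transformed metabolite on
standardized log adiponectin (`fit_study()`), then random-effects pooling
across studies (`pool_estimates()`). The genetic arm is two-sample MR:
per-study regressions of each transformed metabolite on allele dosage
(`snp_outcome_regressions()`), harmonized to an external instrument set
(`harmonize()`), combined per metabolite by fixed-effect IVW over the
SNP-specific Wald ratios (`ivw_combine()`), then the same random-effects
pooling across studies. Fixed-effect combination *within* a study and
random-effects *across* studies mirrors the fact that SNP-level estimates
within a study share one population, while studies differ.

## The generative model

`sim_config()`/`simulate_cohorts()` define the world the pipeline is tested
in. On the standardized scale, for each participant:

* genotypes `G_j ~ Binomial(2, p_j)` at 4 unlinked SNPs (Hardy-Weinberg),
  with default effect-allele frequencies 0.67, 0.10, 0.85, 0.39 — the first,
  second and fourth inside the ranges reported for European cohort studies
  of the *ADIPOQ* instruments; the third is a documented placeholder, since
  no published value is wired in, and all four are configurable;
* a latent standard-normal confounder `C` (adiposity/insulin resistance);
* standardized log adiponectin `A = sum_j gamma_j G*_j + delta C + e`, with
  the standardized-scale `gamma_j` equal across SNPs and calibrated so the
  instruments jointly explain `snp_r2_adiponectin` (default 0.04) of the
  variance of `A`; reported adiponectin is `exp(meanlog + sdlog * A)`
  (default median ≈ 8 µg/mL, log-SD 0.55, typical of ELISA panels);
* metabolites `M_i = theta_i A + lambda_i C + u_i`, where `theta_i` is the
  true causal effect (default 0), `lambda_i` the confounder loading
  (default 0.6 with `delta = 0.5`, giving a confounded observational slope
  `theta + delta lambda = 0.3`), and `u_i` block-structured noise scaled so
  every metabolite has unit marginal variance.

Every variance budget is checked at configuration time; a component set
that exceeds 1 for any variable is an error naming that variable.

Both estimands are therefore analytic: the population multivariable slope
is `theta_i + delta * lambda_i`, the MR estimand is `theta_i`, and
`sim_truth()` exposes both so tests compare each arm against its own truth
rather than against the other arm.

### Heterogeneity mechanism

Between-study heterogeneity enters as a per-study additive normal
perturbation of the confounder loadings, `lambda_is = lambda_i + eta_is`
with `eta_is ~ N(0, study_heterogeneity_sd^2)` (default SD 0.05). This
moves the per-study observational truth while leaving the causal truth
untouched, so the observational arm shows nonzero I² from a known mechanism
and the MR arm stays homogeneous. Two consequences are worth noting. First,
the noise share of each metabolite is budgeted at the base `lambda_i`, so a
perturbed study's marginal metabolite variance sits slightly off 1; the
induced attenuation of the expected confounded slope is second order
(about 0.2% at the default SD) and is covered by the Monte-Carlo tolerances
in the tests. Second, the perturbation operates even when `lambda_i = 0`:
a truly null generator must also set `study_heterogeneity_sd = 0`.

### Block correlation and the effective number of tests

The noise vectors share a per-block factor: `u` in a block has pairwise
correlation `within_block_corr` (default 0.85), so the implied
metabolite-metabolite correlation within a block is
`lambda_i lambda_j + rho sqrt(v_i v_j)` — roughly 0.9 within blocks and
0.36 across blocks at the defaults. This emulates the extreme collinearity
of NMR lipoprotein subclass measures, where lipid content of adjacent
subclasses correlates above 0.9. With the default seven-block partition of
74 measures, the principal-component rule (below) lands at a few dozen
effective tests — the same order as real NMR panels — rather than 74.

What the generator deliberately does **not** emulate: assay
missingness mechanisms, non-normal metabolite tails beyond what the rank
transformation removes, linkage disequilibrium between instruments (the
four SNPs are independent by design), fractional imputed dosages,
covariate effects on metabolites (age, sex, centre and ancestry PCs are
simulated but carry no effects by default, so adjustment is testably
neutral; BMI tracks the latent confounder), or pleiotropic instrument
paths. Passing tests therefore show the estimators do what they claim
under a clean instrumental-variable structure; they do not certify
robustness to pleiotropy or selection, which the cis-instrument design
addresses by construction rather than by statistics.

## Preprocessing choices

Covariate adjustment is per-study OLS residualization (intercept always
included), with participants missing a metabolite or covariate excluded for
that metabolite only — so usable n varies by metabolite, as it does in real
multi-cohort panels. Zero-variance covariates are dropped with a warning;
a rank-deficient design errors naming the collinear columns.

The inverse rank-based normal transformation maps rank `r` of `n` to
`qnorm((r - c)/(n - 2c + 1))`. The offset `c = 3/8` (Blom) is the
convention in genetic epidemiology and is configurable; ties receive the
mean of their ranks, which preserves ordering and keeps tied observations
identical. With distinct values the transformed column has mean exactly 0;
with ties the mean is only approximately 0, which is why the generator's
continuous metabolites are the reference case. For stratified re-runs the
transformation is applied within each analysis stratum.

The effective number of independent tests is the smallest `k` such that
the top-`k` eigenvalues of the metabolite correlation matrix exceed — in
cumulative share, strictly — 0.95 of total variance. "Over 95%" is read as
strictly greater; with 74 mutually uncorrelated measures this gives
`k = 71` (71/74 = 95.95%), and a rank-1 panel gives `k = 1`. PCA is on the
correlation matrix of complete-case participants: the measures are already
standardized, so correlation and covariance PCA coincide up to
missingness, and complete-case avoids an imputation model. Eigenvalues are
clipped at zero to guard against numerically negative values from singular
panels. When several reference studies are designated,
`shared_testing_plan()` takes the maximum `k` across them — the most
conservative reading consistent with one shared threshold. The per-test
alpha is stored at full precision and displayed to 2 significant figures.

## MR choices

The Wald-ratio SE defaults to the first-order delta form `se_y/|beta_x|`,
which ignores the uncertainty of the external SNP-exposure estimate; this
is the primary form of the cited IVW estimator, and a `second_order`
option adds the `beta_y^2 se_x^2 / beta_x^4` term (the two agree within 5%
whenever the instrument F-statistic is large). Instruments with
`|beta_x|/se_x < 2` trigger a weak-instrument warning. Harmonization
sign-flips outcome effects coded on the other allele, complements their
EAF, and drops palindromic (A/T, C/G) SNPs whose instrument EAF lies in
[0.42, 0.58] — the conventional window in which strand cannot be resolved
from frequency; the default instrument panel contains no palindromes, so
the rule only bites on user-supplied data. A single surviving SNP reduces
IVW exactly to the Wald ratio; zero surviving SNPs is an error.

The instrument-confounder balance check regresses each classical
confounder on dosage — linear for continuous, logistic (log-odds per
allele) for binary — and should show only chance associations when the
generator has no SNP-to-confounder path; `confounder_snp_effect` wires the
first SNP into BMI to give the check something to find in power tests.

## Meta-analysis and comparison choices

DerSimonian-Laird pooling uses the moment estimator
`tau2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))` with
fixed-effect weights `w = se^-2`, and `I2 = max(0, (Q-(k-1))/Q) * 100`.
Pooled p-values use a two-sided normal reference, the standard choice for
DL; no Hartung-Knapp or REML variants are offered. A single contributing
study passes through unchanged with `Q = tau2 = I2 = 0`, and studies
missing a metabolite are silently absent from that metabolite's pool, so
`k` varies per row. Heterogeneity is classed substantial for I² in
[50, 75] and high above 75.

The per-metabolite Z test treats the arms as independent information
sources — the unpooled two-sample form — which is an approximation
wherever the same cohorts contribute to both arms; the two-sample MR
framing keeps the overlap-induced correlation small. The profile-level
correlation of estimates is computed on the point estimates, unweighted,
matching a scatter of one arm against the other.

## Problem sizes used by the test suite

The suite's simulation-based checks run at sizes chosen to make
Monte-Carlo error small relative to the asserted tolerances while keeping
the default run fast: calibration of the generator at single samples of
10,000-30,000; the parameter-recovery study at 200 replicates of 5 studies
× 5,000 participants with a 5-metabolite panel (the estimands are
per-metabolite, so panel width does not change what is measured); the
power-asymmetry check at one full 74-metabolite panel over 5 studies ×
5,000; and the balance-test null calibration at 200 seeds of n = 800.
`scripts/acceptance.R` re-runs the pipeline at the default configuration
(5 studies × 2,000, 74 metabolites) and writes the quantities it computes.

## Known limitations

* The comparison Z test ignores between-arm correlation from overlapping
  samples (conservative or anticonservative depending on the direction of
  the shared component).
* The default instrument frequencies include one placeholder, and per-SNP
  exposure effects are calibrated to the joint R² rather than to published
  per-SNP values.
* No pleiotropy-robust estimators (MR-Egger, weighted median) are
  provided: the design restricts to cis instruments instead.
* The generator's confounder is a single latent factor; multi-factor
  confounding would require a config extension, not a code change to the
  estimators.
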