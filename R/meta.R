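.dl_core <- function(beta, se) {
  k <- length(beta)
  if (k == 0) stop("no estimates to pool", call. = FALSE)
  if (any(se <= 0)) stop("all standard errors must be positive", call. = FALSE)
  if (k == 1) {
    return(list(beta = beta, se = se, k = 1L, Q = 0, tau2 = 0, i2 = 0))
  }
  w <- 1 / se^2
  b_fe <- sum(w * beta) / sum(w)
  Q <- sum(w * (beta - b_fe)^2)
  denom <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (Q - (k - 1)) / denom)
  i2 <- if (Q > 0) max(0, (Q - (k - 1)) / Q) * 100 else 0
  wr <- 1 / (se^2 + tau2)
  list(beta = sum(wr * beta) / sum(wr), se = sqrt(1 / sum(wr)),
       k = as.integer(k), Q = Q, tau2 = tau2, i2 = i2)
}

.het_class <- function(i2) {
  dplyr::case_when(i2 > 75 ~ "high",
                   i2 >= 50 ~ "substantial",
                   TRUE ~ "low")
}

#' DerSimonian-Laird random-effects pooling of one estimate set
#'
#' Moment-based random-effects meta-analysis: Cochran's Q on fixed-effect
#' inverse-variance weights, `tau2 = max(0, (Q - (k-1)) / (sum(w) -
#' sum(w^2)/sum(w)))`, pooled estimate with weights `1 / (se^2 + tau2)`, and
#' `I2 = max(0, (Q - (k-1)) / Q) * 100`. The pooled p-value uses a two-sided
#' normal reference. A single estimate passes through unchanged with
#' `Q = tau2 = I2 = 0`. Heterogeneity is classed `"substantial"` for I2 in
#' [50, 75] and `"high"` above 75.
#'
#' @param estimates A data frame of study-specific estimates for one
#'   metabolite and one arm, with columns `beta` and `se` (and optionally
#'   `metabolite`, `arm`, `n`).
#' @return A one-row tibble with `metabolite`, `arm`, `beta`, `se`, `p`, `k`,
#'   `Q`, `tau2`, `i2`, `het_class`, `n_total`.
#' @export
dl_pool <- function(estimates) {
  d <- .dl_core(estimates$beta, estimates$se)
  tibble::tibble(
    metabolite = if ("metabolite" %in% names(estimates))
      estimates$metabolite[1] else NA_character_,
    arm = if ("arm" %in% names(estimates)) estimates$arm[1] else NA_character_,
    beta = d$beta, se = d$se, p = .two_sided_p(d$beta, d$se),
    k = d$k, Q = d$Q, tau2 = d$tau2, i2 = d$i2,
    het_class = .het_class(d$i2),
    n_total = if ("n" %in% names(estimates))
      as.integer(sum(estimates$n)) else NA_integer_
  )
}

#' Pool study-specific estimates across all metabolites and arms
#'
#' Applies [dl_pool()] within each `(metabolite, arm)` group. Studies that
#' contributed no estimate for a metabolite are simply absent from that
#' metabolite's pool, so `k` can vary across rows.
#'
#' @param estimates Stacked association estimates (both arms welcome) with
#'   columns `metabolite`, `arm`, `beta`, `se` and optionally `n`.
#' @return A tibble of pooled estimates, one row per `(metabolite, arm)`.
#' @export
pool_estimates <- function(estimates) {
  estimates |>
    dplyr::group_by(.data$metabolite, .data$arm) |>
    dplyr::group_modify(function(d, key) {
      out <- dl_pool(d)
      out[, setdiff(names(out), c("metabolite", "arm"))]
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$arm, .data$metabolite)
}
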