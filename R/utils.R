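# Internal least-squares helpers shared by the observational and MR arms.

# slope of each column of Y on x, with intercept; per-column complete cases
.ols_slopes <- function(x, Y, names = colnames(Y)) {
  Y <- as.matrix(Y)
  one_col <- function(j) {
    ok <- stats::complete.cases(x, Y[, j])
    xi <- x[ok]; yi <- Y[ok, j]
    n <- length(xi)
    if (n < 3 || stats::var(xi) == 0) {
      return(c(beta = NA_real_, se = NA_real_, n = n))
    }
    xc <- xi - mean(xi)
    sxx <- sum(xc^2)
    yc <- yi - mean(yi)
    beta <- sum(xc * yc) / sxx
    rss <- max(sum(yc^2) - beta^2 * sxx, 0)
    c(beta = beta, se = sqrt(rss / (n - 2) / sxx), n = n)
  }
  if (!anyNA(Y) && !anyNA(x)) {
    n <- length(x)
    xc <- x - mean(x)
    sxx <- sum(xc^2)
    if (sxx == 0) stop("regressor has zero variance", call. = FALSE)
    yc <- sweep(Y, 2, colMeans(Y))
    beta <- drop(crossprod(yc, xc)) / sxx
    rss <- pmax(colSums(yc^2) - beta^2 * sxx, 0)
    se <- sqrt(rss / (n - 2) / sxx)
    return(tibble::tibble(metabolite = names, beta = unname(beta),
                          se = unname(se), n = n))
  }
  res <- t(vapply(seq_len(ncol(Y)), one_col, numeric(3)))
  tibble::tibble(metabolite = names, beta = res[, "beta"], se = res[, "se"],
                 n = as.integer(res[, "n"]))
}

# canonical participant order so estimates are invariant to row permutation
.sort_by_id <- function(df) {
  if (all(c("study_id", "id") %in% names(df))) {
    df[order(df$study_id, df$id), , drop = FALSE]
  } else if ("id" %in% names(df)) {
    df[order(df$id), , drop = FALSE]
  } else {
    df
  }
}

.two_sided_p <- function(beta, se) 2 * stats::pnorm(-abs(beta / se))
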