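test_that("inverse normal transform follows the Blom rank formula", {
  # n = 5 distinct values: largest maps to qnorm((5 - 3/8) / (5 + 1/4))
  x <- c(3, 1, 4, 1.5, 9)
  z <- inverse_normal_transform(x)
  expect_equal(z[which.max(x)], stats::qnorm(4.625 / 5.25))
  expect_equal(z[which.min(x)], stats::qnorm(0.625 / 5.25))
  # odd n, distinct values: the middle observation maps to exactly 0
  expect_equal(z[order(x)][3], 0)
  # order preservation
  expect_identical(order(z), order(x))
})

test_that("transform handles ties, missing values, and degenerate input", {
  x <- c(2, 2, 5, 7, NA)
  z <- inverse_normal_transform(x)
  expect_identical(z[1], z[2])    # tied values share the mean rank
  expect_true(is.na(z[5]))
  # mean is exactly zero for distinct values (symmetric rank offsets)
  expect_equal(mean(inverse_normal_transform(c(9, 1, 4, 2, 6))), 0,
               tolerance = 1e-10)
  expect_error(inverse_normal_transform(rep(4, 10)), "identical")
  expect_error(inverse_normal_transform(c(1, 2)), "at least 3")
})

test_that("transform output has standard-normal quantiles", {
  z <- inverse_normal_transform(stats::rexp(2001))
  expect_equal(stats::median(z), 0, tolerance = 1e-12)
  expect_equal(stats::sd(z), 1, tolerance = 0.01)
})

test_that("Spearman correlation is invariant under the transform", {
  withr::with_seed(9, {
    x <- stats::rlnorm(500)
    y <- x + stats::rnorm(500)
  })
  before <- stats::cor(x, y, method = "spearman")
  after <- stats::cor(inverse_normal_transform(x),
                      inverse_normal_transform(y), method = "spearman")
  expect_equal(after, before, tolerance = 1e-12)
})

test_that("residualize with no covariates centres the metabolites", {
  co <- one_cohort(n = 50, seed = 3)
  res <- residualize(co, character())
  m <- metabolite_cols(co)
  co_sorted <- co[order(co$id), ]
  expect_equal(as.matrix(res[m]),
               scale(as.matrix(co_sorted[m]), scale = FALSE),
               ignore_attr = TRUE)
})

test_that("a metabolite exactly linear in a covariate residualizes to zero", {
  co <- one_cohort(n = 80, seed = 4)
  co$met_001 <- 3 + 0.5 * co$age
  res <- residualize(co, "age")
  expect_lt(max(abs(res$met_001)), 1e-10)
})

test_that("residuals solve the normal equations (orthogonal to covariates)", {
  co <- one_cohort(n = 200, seed = 6)
  covs <- c("age", "sex", "bmi")
  res <- residualize(co, covs)
  co_sorted <- co[order(co$id), ]
  X <- cbind(1, as.matrix(co_sorted[covs]))
  R <- as.matrix(res[metabolite_cols(res)])
  expect_lt(max(abs(crossprod(X, R))), 1e-8 * nrow(X))
  # brute-force normal-equations oracle
  Y <- as.matrix(co_sorted[metabolite_cols(co_sorted)])
  beta <- solve(crossprod(X), crossprod(X, Y))
  expect_equal(R, Y - X %*% beta, ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("residualize handles degenerate covariates and missing values", {
  co <- one_cohort(n = 60, seed = 8)
  co$flat <- 1
  expect_warning(residualize(co, c("age", "flat")), "zero-variance")
  co$age2 <- 2 * co$age
  expect_error(residualize(co, c("age", "age2")), "age2")
  expect_error(residualize(co, "not_there"), "not_there")
  # per-metabolite exclusion: a missing metabolite value only drops that cell
  co$met_002[5] <- NA
  res <- suppressWarnings(residualize(co, "age"))
  expect_true(is.na(res$met_002[res$id == co$id[5]]))
  expect_identical(sum(is.na(res$met_001)), 0L)
  expect_identical(sum(is.na(res$met_002)), 1L)
})

test_that("preprocess_cohort gives mean-zero, rank-preserving columns", {
  co <- one_cohort(n = 150, seed = 12)
  pan <- preprocess_cohort(co, c("age", "sex"))
  res <- residualize(co, c("age", "sex"))
  for (m in metabolite_cols(pan)) {
    expect_lt(abs(mean(pan[[m]])), 1e-8)
    expect_identical(order(pan[[m]]), order(res[[m]]))
  }
  expect_identical(attr(pan, "n_used")[["met_001"]], 150L)
})

test_that("independent measures need almost all components; identical need one", {
  # 74 mutually uncorrelated standardized measures: eigenvalues all 1, so
  # k is the smallest count with k/74 > 0.95, i.e. 71
  expect_identical(n_independent_tests(diag(74)), 71L)
  # rank-1 panel: 74 copies of one variable
  x <- stats::rnorm(100)
  panel <- as.data.frame(replicate(74, x))
  names(panel) <- sprintf("met_%03d", 1:74)
  plan <- effective_tests(panel)
  expect_identical(plan$n_independent_tests, 1L)
})

test_that("the Bonferroni threshold for 27 independent tests is ~0.0019", {
  plan <- adipomet:::.new_testing_plan(74, 27L, 0.05)
  expect_equal(plan$alpha_per_test, 0.05 / 27)
  expect_equal(signif(plan$alpha_per_test, 2), 0.0019)
})

test_that("effective_tests enforces its preconditions", {
  panel <- as.data.frame(matrix(stats::rnorm(5 * 10), 5))
  names(panel) <- sprintf("met_%03d", 1:10)
  expect_error(effective_tests(panel), "more complete-case participants")
})

test_that("shared plan across reference studies takes the maximum k", {
  withr::with_seed(21, {
    # panel A: 6 independent measures (k = 6); panel B: rank-1 (k = 1)
    a <- as.data.frame(matrix(stats::rnorm(400 * 6), 400))
    names(a) <- sprintf("met_%03d", 1:6)
    x <- stats::rnorm(400)
    b <- as.data.frame(replicate(6, x))
    names(b) <- sprintf("met_%03d", 1:6)
  })
  ka <- effective_tests(a)$n_independent_tests
  plan <- shared_testing_plan(list(a, b))
  expect_identical(plan$n_independent_tests, ka)
  # single panel: identical to effective_tests
  expect_identical(shared_testing_plan(list(a))$n_independent_tests, ka)
})

test_that("preprocessing leaves the population correlation structure intact", {
  cfg <- sim_config(n_studies = 1, n_per_study = 4000, n_metabolites = 4,
                    block_sizes = c(2, 2), study_heterogeneity_sd = 0,
                    seed = 33)
  co <- simulate_cohorts(cfg)
  pan <- preprocess_cohort(co, c("age", "sex"))
  raw_cor <- stats::cor(as.matrix(co[order(co$id), ][metabolite_cols(co)]))
  new_cor <- stats::cor(as.matrix(pan[metabolite_cols(pan)]))
  expect_equal(new_cor, raw_cor, tolerance = 0.05)
})
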