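fake_instruments <- function() {
  tibble::tibble(
    rsid = c("rs1", "rs2", "rs3", "rs4"),
    effect_allele = c("A", "G", "A", "C"),
    other_allele = c("C", "A", "T", "G"),
    eaf = c(0.3, 0.6, 0.50, 0.2),   # rs3 is a palindromic A/T at 0.50
    beta = c(0.1, 0.15, 0.2, 0.12),
    se = c(0.01, 0.01, 0.02, 0.01),
    n = 30000L
  )
}

fake_outcomes <- function() {
  tibble::tibble(
    rsid = c("rs1", "rs2", "rs3", "rs4"),
    metabolite = "met_001",
    study_id = "study_01",
    beta_y = c(0.02, 0.2, 0.05, -0.01),
    se_y = c(0.01, 0.02, 0.02, 0.01),
    n = 5000L,
    effect_allele = c("A", "A", "A", "C"),  # rs2 coded on the other allele
    eaf = c(0.3, 0.4, 0.5, 0.2)
  )
}

test_that("harmonization flips other-allele codings and drops palindromes", {
  expect_message(h <- harmonize(fake_instruments(), fake_outcomes()),
                 "rs3")
  expect_false("rs3" %in% h$rsid)
  # rs2 was coded on the instrument's other allele: sign flip + eaf complement
  expect_equal(h$beta_y[h$rsid == "rs2"], -0.2)
  expect_equal(h$eaf[h$rsid == "rs2"], 0.6)
  expect_equal(h$effect_allele[h$rsid == "rs2"], "G")
  # aligned SNPs pass through untouched
  expect_equal(h$beta_y[h$rsid == "rs1"], 0.02)
  expect_identical(attr(h, "dropped")$reason, "palindromic with ambiguous EAF")
})

test_that("harmonization drops unknown and mismatched SNPs, errors on empty", {
  ins <- fake_instruments()[1, ]
  out <- fake_outcomes()[1, ]
  out$effect_allele <- "T"   # neither allele of rs1
  expect_message(expect_error(harmonize(ins, out), "no usable instruments"))
  out2 <- fake_outcomes()
  out2$rsid[1] <- "rs_unknown"
  h <- suppressMessages(harmonize(fake_instruments(), out2))
  expect_false("rs_unknown" %in% h$rsid)
})

test_that("wald ratio is the effect quotient with first-order SE", {
  w <- wald_ratio(1, 0.01, 0.3, 0.1)
  expect_equal(w$ratio, 0.3)
  expect_equal(w$se, 0.1)
  w2 <- wald_ratio(0.5, 0.01, 0.3, 0.1)
  expect_equal(w2$ratio, 0.6)
  expect_equal(w2$se, 0.2)
  expect_error(wald_ratio(0, 0.01, 0.3, 0.1), "nonzero")
  expect_warning(wald_ratio(0.1, 0.06, 0.3, 0.1), "weak instrument")
})

test_that("second-order delta SE agrees with a simulation oracle when strong", {
  bx <- 0.2; sx <- 0.01; by <- 0.1; sy <- 0.02   # |bx|/sx = 20
  w1 <- wald_ratio(bx, sx, by, sy)
  w2 <- wald_ratio(bx, sx, by, sy, second_order = TRUE)
  sim_sd <- withr::with_seed(40, {
    stats::sd(stats::rnorm(2e5, by, sy) / stats::rnorm(2e5, bx, sx))
  })
  expect_equal(w2$se, sim_sd, tolerance = 0.05)
  expect_equal(w1$se, sim_sd, tolerance = 0.05)
})

test_that("IVW combination matches its closed form and the WLS oracle", {
  h <- tibble::tibble(beta_x = c(0.1, 0.2), beta_y = c(0.05, 0.08),
                      se_y = c(0.01, 0.02))
  est <- ivw_combine(h)
  expect_equal(est$beta, 0.45)
  expect_equal(est$se, sqrt(1 / 200))
  # oracle: weighted least squares through the origin
  fit <- stats::lm(beta_y ~ beta_x - 1, data = h, weights = 1 / h$se_y^2)
  expect_equal(est$beta, unname(stats::coef(fit)), tolerance = 1e-12)
})

test_that("IVW reduces to the Wald ratio with one SNP and is null on zeros", {
  h1 <- tibble::tibble(beta_x = 0.5, se_x = 0.02, beta_y = 0.3, se_y = 0.1)
  est <- ivw_combine(h1)
  w <- wald_ratio(h1$beta_x, h1$se_x, h1$beta_y, h1$se_y)
  expect_equal(est$beta, w$ratio)
  expect_equal(est$se, w$se)
  h0 <- tibble::tibble(beta_x = c(0.1, 0.2), beta_y = 0, se_y = 0.01)
  est0 <- ivw_combine(h0)
  expect_equal(est0$beta, 0)
  expect_equal(est0$p, 1)
})

test_that("SNP-outcome regressions respect allele symmetry and alignment", {
  co <- one_cohort(n = 300, seed = 55)
  pan <- preprocess_cohort(co)
  a <- snp_outcome_regressions(co, pan)
  # recoding dosage as 2 - G flips every beta exactly
  co2 <- co
  co2$dosage_rs6810075 <- 2L - co2$dosage_rs6810075
  b <- snp_outcome_regressions(co2, pan)
  i <- a$rsid == "rs6810075"
  expect_equal(b$beta_y[i], -a$beta_y[i], tolerance = 1e-12)
  expect_equal(b$se_y[i], a$se_y[i], tolerance = 1e-12)
  # a panel covering different participants is refused
  pan_bad <- pan[-1, ]
  expect_error(snp_outcome_regressions(co, pan_bad), "align")
})

test_that("monomorphic SNPs are excluded with a warning", {
  co <- one_cohort(n = 100, seed = 56)
  co$dosage_rs16861209 <- 0L
  pan <- preprocess_cohort(co)
  expect_warning(a <- snp_outcome_regressions(co, pan), "rs16861209")
  expect_false("rs16861209" %in% a$rsid)
  expect_identical(nrow(a), 3L * 8L)
})

test_that("mr_study applies IVW per metabolite with harmonized instruments", {
  co <- one_cohort(n = 500, seed = 57)
  cfg <- attr(co, "config")
  ins <- export_instrument_summary(cfg, 5000)
  assoc <- export_summary_study(co)
  est <- mr_study(ins, assoc)
  expect_identical(nrow(est), 8L)
  expect_true(all(est$arm == "mr"))
  expect_true(all(est$n_snps_used == 4L))
  # agrees with a manual harmonize + ivw_combine for one metabolite
  h <- harmonize(ins, assoc[assoc$metabolite == "met_004", ])
  manual <- ivw_combine(h)
  expect_equal(est$beta[est$metabolite == "met_004"], manual$beta)
  expect_equal(est$se[est$metabolite == "met_004"], manual$se)
})

test_that("confounder balance uses the right model per confounder type", {
  co <- one_cohort(n = 400, seed = 58)
  bal <- confounder_balance(co)
  expect_identical(nrow(bal), 4L * 5L)
  expect_setequal(unique(bal$type[bal$confounder %in% c("sex", "smoking")]),
                  "logistic")
  expect_setequal(unique(bal$type[bal$confounder %in% c("age", "bmi", "pc1")]),
                  "linear")
  # constant confounder is skipped with a warning
  co$bmi <- 25
  expect_warning(bal2 <- confounder_balance(co), "bmi")
  expect_false("bmi" %in% bal2$confounder)
})

test_that("a SNP wired to BMI is detected by the balance check", {
  co <- one_cohort(n = 10000, seed = 59, confounder_snp_effect = 0.5)
  bal <- confounder_balance(co, confounders = "bmi")
  p_wired <- bal$p[bal$rsid == "rs6810075"]
  expect_lt(p_wired, 1e-4)
  expect_equal(bal$estimate[bal$rsid == "rs6810075"], 0.5, tolerance = 0.5)
})
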