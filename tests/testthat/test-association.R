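make_fitted_two_group <- function(seed = 31, n = 300, coef = log(2)) {
  sc <- two_group_scenario(seed = seed, n_subjects = n, exposure_coef = coef)
  co <- simulate_cohort(sc)
  cp <- center_trajectories(co$panel)
  base <- fit_em(cp, K = 2, cov_kind = "independence", n_starts = 4,
                 seed = seed)
  des <- concomitant_design(co$baseline, exposures = "exposure")
  fit <- refit_with_covariates(cp, des, K = 2, cov_kind = "independence",
                               seed = seed + 1, base_fit = base)
  list(cohort = co, cpanel = cp, base = base, design = des, fit = fit)
}

test_that("concomitant design validates columns, rank and completeness", {
  b <- as_baseline_table(data.frame(
    subject_id = sprintf("s%02d", 1:20), sex = "female",
    expo = rnorm(20), conf = rnorm(20), ones = 1))
  d <- concomitant_design(b, "expo", "conf")
  expect_equal(colnames(d), c("(Intercept)", "expo", "conf"))
  expect_true(all(d[, 1] == 1))
  expect_error(concomitant_design(b, "nope"), class = "trajmix_config_error")
  # interaction with a constant column duplicates the exposure column
  expect_error(concomitant_design(b, "expo", "ones",
                                  interactions = list(c("expo", "ones"))),
               class = "trajmix_rank_deficient")
  # complete-case drop is recorded
  b$expo[3] <- NA
  expect_message(d2 <- concomitant_design(b, "expo"), "complete-case")
  expect_equal(attr(d2, "dropped_subjects"), "s03")
  expect_equal(nrow(d2), 19)
})

test_that("intercept-only refit reproduces the covariate-free likelihood", {
  sc <- two_group_scenario(seed = 41, n_subjects = 150, exposure_coef = log(2))
  co <- simulate_cohort(sc)
  cp <- center_trajectories(co$panel)
  base <- fit_em(cp, K = 2, cov_kind = "independence", n_starts = 4, seed = 8)
  d0 <- concomitant_design(co$baseline, exposures = character())
  f0 <- refit_with_covariates(cp, d0, K = 2, cov_kind = "independence",
                              seed = 9, base_fit = base)
  expect_lt(abs(f0$loglik - base$loglik), 1e-6)
})

test_that("RRR equals the exponentiated coefficient and obeys Eq-style ratios", {
  m <- make_fitted_two_group()
  r <- rrr(m$fit, "exposure")
  expect_equal(unname(r), exp(unname(m$fit$model$gamma[, "exposure"])))
  expect_error(rrr(m$fit, "absent"), class = "trajmix_lookup_error")

  # direct probability-ratio evaluation at arbitrary z agrees to 1e-12
  set.seed(77)
  for (rep in 1:25) {
    K <- sample(2:5, 1)
    gamma <- matrix(rnorm(2 * (K - 1)), K - 1, 2)
    z <- rnorm(1)
    j <- sample(K - 1, 1)
    expect_equal(oracle_rrr_ratio(gamma, z, j), exp(gamma[j, 2]),
                 tolerance = 1e-12)
  }
})

test_that("Wald intervals are log-symmetric and carry sensible p-values", {
  m <- make_fitted_two_group()
  ci <- wald_ci(m$fit, "exposure")
  expect_true(all(ci$ci_low <= ci$rrr & ci$rrr <= ci$ci_high))
  expect_equal(log(ci$ci_high) - log(ci$rrr), log(ci$rrr) - log(ci$ci_low),
               tolerance = 1e-10)
  expect_true(all(ci$p_value > 0 & ci$p_value < 1))
  expect_true(all(ci$se_log > 0))
  # the cheap two-stage variant is also log-symmetric and of the same
  # order of magnitude
  ci2 <- wald_ci(m$fit, "exposure", method = "two_stage")
  expect_equal(log(ci2$ci_high) - log(ci2$rrr),
               log(ci2$rrr) - log(ci2$ci_low), tolerance = 1e-10)
  expect_lt(abs(log(ci2$se_log) - log(ci$se_log)), log(5))
})

test_that("rescaling a covariate rescales gamma and leaves per-unit RRR fixed", {
  m <- make_fitted_two_group(seed = 51, n = 250)
  b2 <- m$cohort$baseline
  b2$exposure <- b2$exposure / 2
  d2 <- concomitant_design(b2, exposures = "exposure")
  f2 <- refit_with_covariates(m$cpanel, d2, K = 2,
                              cov_kind = "independence", seed = 52,
                              base_fit = m$base)
  g1 <- m$fit$model$gamma[, "exposure"]
  g2 <- f2$model$gamma[, "exposure"]
  expect_equal(unname(g2), unname(2 * g1), tolerance = 1e-3)
  expect_equal(unname(rrr(f2, "exposure", delta = 0.5)),
               unname(rrr(m$fit, "exposure", delta = 1)), tolerance = 1e-3)
})

test_that("adjusted/unadjusted table mirrors the per-compound layout", {
  co <- simulate_cohort(default_growth_scenario(seed = 61, n_subjects = 240))
  tab <- adjusted_and_unadjusted(
    co$panel, co$baseline,
    exposures = c("log10_opDDT", "log10_ppDDT", "log10_ppDDE"),
    confounders = c("years_usa", "mat_bmi", "birth_weight_kg",
                    "breastfeed_months"),
    K = 4, cov_kind = "independence", seed = 62, ci_method = "two_stage",
    n_starts = 3, burn_iter = 8)
  # K-1 groups x 3 exposures x 2 sexes x 2 adjustment states
  expect_equal(nrow(tab), 3 * 3 * 2 * 2)
  expect_setequal(unique(tab$sex), c("male", "female"))
  expect_true(all(tab$rrr > 0))
  expect_true(all(tab$ci_low <= tab$rrr & tab$rrr <= tab$ci_high))
  expect_equal(sum(tab$adjusted), nrow(tab) / 2)
})

test_that("interaction scan reports one comparison row set per modifier", {
  sc <- two_group_scenario(seed = 71, n_subjects = 250, exposure_coef = log(2))
  co <- simulate_cohort(sc)
  b <- co$baseline
  set.seed(72)
  b$mod1 <- rnorm(nrow(b))
  b$mod2 <- rnorm(nrow(b))
  out <- interaction_scan(co$panel, b, exposure = "exposure",
                          modifiers = c("mod1", "mod2"), K = 2,
                          cov_kind = "independence", seed = 73,
                          ci_method = "two_stage", n_starts = 3,
                          burn_iter = 8)
  expect_equal(nrow(out), 2L)   # (K-1) rows per modifier
  expect_setequal(out$modifier, c("mod1", "mod2"))
  # pure-noise modifiers: interactions should be near zero
  expect_true(all(abs(out$gamma_interaction) < 2.5 * out$se))
  expect_true(all(is.finite(out$bic_base) & is.finite(out$bic_interaction)))
})
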