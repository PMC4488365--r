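test_that("K = 1 fit reduces to a single GLS fit with unit posteriors", {
  co <- simulate_cohort(default_growth_scenario(seed = 3, n_subjects = 60))
  cp <- center_trajectories(co$panel)
  f <- fit_em(cp, K = 1, cov_kind = "independence", seed = 1)
  expect_true(f$converged)
  expect_lte(f$n_iter, 2L)
  expect_equal(unname(f$posteriors), matrix(1, f$n_subjects, 1))
  # coefficients equal ordinary least squares on the whole centered panel
  X <- eval_basis(f$model$basis, cp$age)
  expect_equal(as.numeric(f$model$beta), as.numeric(qr.solve(X, cp$value)),
               tolerance = 1e-8)
})

test_that("well-separated two-group data are recovered almost perfectly", {
  sc <- two_group_scenario(seed = 30, n_subjects = 200, exposure_coef = 0)
  sc$noise$sigma <- 0.4   # curve gap is many noise SDs
  co <- simulate_cohort(sc)
  cp <- center_trajectories(co$panel)
  f <- fit_em(cp, K = 2, cov_kind = "independence", n_starts = 8, seed = 2)
  expect_true(f$converged)
  acc <- oracle_match_accuracy(f$labels, co$true_labels, 2)
  expect_gte(acc, 0.99)
  # relabeling convention: group 1 has the higher curve at the max age
  cg <- group_curves(f, ages = 9)
  expect_gt(cg$value[cg$group == 1], cg$value[cg$group == 2])
})

test_that("EM trace is monotone and invariant to subject order", {
  co <- simulate_cohort(default_growth_scenario(seed = 14, n_subjects = 80))
  cp <- center_trajectories(co$panel)
  f <- fit_em(cp, K = 3, cov_kind = "independence", n_starts = 5, seed = 4)
  expect_true(all(diff(f$trace) >= -1e-8 * (abs(f$trace[-length(f$trace)]) + 1)))

  # permuting input rows changes nothing (panels sort canonically)
  perm <- sample(nrow(co$panel))
  p2 <- trajectory_panel(co$panel$subject_id[perm], co$panel$age[perm],
                         co$panel$value[perm])
  f2 <- fit_em(center_trajectories(p2), K = 3, cov_kind = "independence",
               n_starts = 5, seed = 4)
  expect_identical(f$loglik, f2$loglik)
  expect_identical(f$posteriors, f2$posteriors)
})

test_that("BIC follows its formula and counts parameters correctly", {
  f <- list(loglik = -100, n_params = 10, n_subjects = 50)
  expect_equal(bic(f), 200 + 10 * log(50))
  # parameter count: K=4, basis dim 4, exponential, no covariates
  co <- simulate_cohort(default_growth_scenario(seed = 3, n_subjects = 60))
  cp <- center_trajectories(co$panel)
  f4 <- fit_em(cp, K = 4, cov_kind = "exponential", n_starts = 2,
               burn_iter = 5, max_iter = 40, seed = 5)
  expect_equal(f4$n_params, 16 + 8 + 3)
  f4i <- fit_em(cp, K = 4, cov_kind = "independence", n_starts = 2,
                burn_iter = 5, max_iter = 40, seed = 5)
  expect_equal(f4i$n_params, 16 + 4 + 3)
})

test_that("BIC penalizes a spurious second group on one-group null data", {
  wins <- 0L
  for (r in 1:20) {
    sc <- simulation_scenario(
      n_subjects = 120, K_true = 1, p_visit_missing = 0,
      group_mean_curves = list(list(curve = function(t) 0.3 * (t - 5.3),
                                    base = 18)),
      level_sd = 1.5, noise = list(kind = "independence", sigma = 0.6),
      seed = 100 + r)
    cp <- center_trajectories(simulate_cohort(sc)$panel)
    f1 <- fit_em(cp, K = 1, cov_kind = "independence", seed = r)
    f2 <- suppressWarnings(fit_em(cp, K = 2, cov_kind = "independence",
                                  n_starts = 5, seed = r))
    if (bic(f2) > bic(f1)) wins <- wins + 1L
  }
  expect_gte(wins, 18L)
})

test_that("selection table covers the grid and classification summarizes posteriors", {
  co <- simulate_cohort(default_growth_scenario(seed = 19, n_subjects = 120))
  cp <- center_trajectories(co$panel)
  sel <- suppressWarnings(select_model(cp, K_range = 2:3,
                                       cov_kinds = c("independence",
                                                     "exponential"),
                                       n_starts = 4, burn_iter = 8,
                                       seed = 6))
  expect_equal(nrow(sel$table), 4L)
  expect_true(all(sel$table$converged))
  expect_equal(sel$fit$bic, min(sel$table$bic))

  cl <- classify(sel$fit)
  expect_true(all(cl$uncertainty$frac_between_0.1_0.9 >= 0 &
                    cl$uncertainty$frac_between_0.1_0.9 <= 1))
  expect_equal(unname(cl$labels), max.col(sel$fit$posteriors,
                                          ties.method = "first"))
})

test_that("classification tie-breaks toward the lowest group index", {
  fake <- list(posteriors = matrix(c(0.5, 0.95, 0.5, 0.05), 2, 2,
                                   dimnames = list(c("a", "b"), NULL)))
  cl <- classify(fake)
  expect_equal(unname(cl$labels), c(1L, 1L))
  # fraction of group-1 posteriors strictly inside (0.1, 0.9)
  expect_equal(cl$uncertainty$frac_between_0.1_0.9[1L], 0.5)
})

test_that("transformation invariance: subject-level shifts do not change the fit", {
  # values and shifts on a dyadic grid with four visits per subject make
  # within-subject centering exactly shift-invariant in floating point
  sc <- default_growth_scenario(seed = 23, n_subjects = 60)
  sc$p_visit_missing <- 0
  co <- simulate_cohort(sc)
  p <- co$panel[co$panel$age != 5, ]
  p$value <- round(p$value * 1024) / 1024
  panel1 <- trajectory_panel(p$subject_id, p$age, p$value)
  set.seed(99)
  shift <- round(rnorm(60, 0, 10) * 1024) / 1024
  names(shift) <- unique(panel1$subject_id)
  p2 <- panel1
  p2$value <- p2$value + shift[p2$subject_id]
  panel2 <- trajectory_panel(p2$subject_id, p2$age, p2$value)

  c1 <- center_trajectories(panel1)
  c2 <- center_trajectories(panel2)
  expect_identical(c1$value, c2$value)
  f1 <- fit_em(c1, K = 4, cov_kind = "independence", n_starts = 4, seed = 7)
  f2 <- fit_em(c2, K = 4, cov_kind = "independence", n_starts = 4, seed = 7)
  expect_identical(f1$model$beta, f2$model$beta)
  expect_identical(f1$posteriors, f2$posteriors)
})
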