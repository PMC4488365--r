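test_that("centering removes level and inverts exactly", {
  p <- toy_panel(list(a = c(17, 19, 21), b = rep(17, 5)))
  cp <- center_trajectories(p)
  expect_equal(cp$value[cp$subject_id == "a"], c(-2, 0, 2))
  expect_equal(cp$value[cp$subject_id == "b"], rep(0, 5))
  # per-subject sums are zero to tight tolerance
  expect_lt(max(abs(tapply(cp$value, cp$subject_id, sum))), 1e-10)
  # exact inversion
  expect_equal(uncenter_trajectories(cp)$value, p$value)
  # adding a constant to one subject leaves its centered values unchanged
  p2 <- p
  p2$value[p2$subject_id == "a"] <- p2$value[p2$subject_id == "a"] + 100
  cp2 <- center_trajectories(p2)
  expect_equal(cp2$value[cp2$subject_id == "a"],
               cp$value[cp$subject_id == "a"])
})

test_that("single-record subjects are dropped from centering with a warning", {
  p <- toy_panel(list(a = c(17, 18), b = 19))
  expect_warning(cp <- center_trajectories(p), "single record")
  expect_setequal(unique(cp$subject_id), "a")
  expect_equal(attr(cp, "dropped_subjects"), "b")
})

test_that("quadratic basis has dimension 4, median knot, partition of unity", {
  ages <- rep(c(2, 3.5, 5, 7, 9), each = 100)
  b <- build_spline_basis(ages)
  expect_equal(b$dimension, 4L)
  expect_equal(b$internal_knots, 5)
  expect_equal(b$boundary_knots, c(2, 9))
  at <- seq(2, 9, length.out = 41)
  X <- eval_basis(b, at)
  expect_equal(rowSums(X), rep(1, length(at)))
  expect_true(all(X >= 0))
  expect_error(build_spline_basis(c(2, 2, 9)), class = "trajmix_basis_error")
})

test_that("covariance models produce the stated matrices", {
  ind <- covariance_model("independence", 2)
  expect_equal(covariance_matrix(ind, c(2, 5, 9)), diag(2, 3))
  ex <- covariance_model("exponential", 2, phi = 2)
  S <- covariance_matrix(ex, c(0, 2))
  expect_equal(S[1, 2], 2 * exp(-1), tolerance = 1e-12)
  expect_equal(S[1, 1], 2)
  # phi -> 0 approaches independence
  ex0 <- covariance_model("exponential", 2, phi = 1e-6)
  expect_equal(covariance_matrix(ex0, c(2, 5, 9)), diag(2, 3),
               tolerance = 1e-10)
  expect_error(covariance_model("independence", -1),
               class = "trajmix_domain_error")
  expect_error(covariance_model("exponential", 1, phi = 0),
               class = "trajmix_domain_error")
  # positive definiteness for exponential at distinct ages
  ev <- eigen(covariance_matrix(covariance_model("exponential", 1.3, phi = 4),
                                c(2, 3.5, 5, 7, 9)))$values
  expect_true(all(ev > 0))
})

test_that("mixture log-likelihood matches a direct oracle for K = 1 and is additive", {
  co <- simulate_cohort(default_growth_scenario(seed = 2, n_subjects = 25))
  cp <- center_trajectories(co$panel)
  basis <- build_spline_basis(cp$age)
  beta <- matrix(c(-3, -1, 2, 4), 4, 1)
  model <- mixture_model(beta, list(covariance_model("independence", 1.3)),
                         matrix(0, 0, 1), basis)
  ll <- mixture_loglik(model, cp)
  # oracle: plain sum of multivariate normal log-densities
  ids <- unique(cp$subject_id)
  ll_oracle <- sum(vapply(ids, function(id) {
    rows <- cp[cp$subject_id == id, ]
    oracle_dmvnorm_log(rows$value,
                       as.numeric(eval_basis(basis, rows$age) %*% beta),
                       diag(1.3, nrow(rows)))
  }, numeric(1)))
  expect_equal(ll, ll_oracle, tolerance = 1e-10)

  # two identical subjects contribute exactly twice one subject's term
  one <- toy_panel(list(u = c(-1, 0, 1, 2, -2)))
  two <- toy_panel(list(u = c(-1, 0, 1, 2, -2), v = c(-1, 0, 1, 2, -2)))
  b3 <- build_spline_basis(rep(c(2, 3.5, 5, 7, 9), 3))
  m1 <- mixture_model(matrix(0, 4, 1), list(covariance_model("independence", 1)),
                      matrix(0, 0, 1), b3)
  expect_equal(mixture_loglik(m1, two), 2 * mixture_loglik(m1, one),
               tolerance = 1e-12)
})

test_that("mixture weights concentrated on one group reduce to that component", {
  co <- simulate_cohort(default_growth_scenario(seed = 2, n_subjects = 25))
  cp <- center_trajectories(co$panel)
  basis <- build_spline_basis(cp$age)
  beta2 <- cbind(c(-3, -1, 2, 4), c(0, 0, 0, 0))
  covs <- list(covariance_model("independence", 1.3),
               covariance_model("independence", 2))
  # intercept +30 puts essentially all weight on group 1
  m_all1 <- mixture_model(beta2, covs, matrix(30, 1, 1), basis)
  m_only1 <- mixture_model(beta2[, 1, drop = FALSE], covs[1],
                           matrix(0, 0, 1), basis)
  expect_equal(mixture_loglik(m_all1, cp), mixture_loglik(m_only1, cp),
               tolerance = 1e-8)
})

test_that("E-step posteriors follow Bayes rule and handle degenerate cases", {
  ages5 <- rep(c(2, 3.5, 5, 7, 9), 2)
  basis <- build_spline_basis(ages5)
  # two identical components, equal weights -> 0.5 everywhere
  beta_same <- cbind(c(1, -1, 0, 2), c(1, -1, 0, 2))
  covs <- list(covariance_model("independence", 1),
               covariance_model("independence", 1))
  m <- mixture_model(beta_same, covs, matrix(0, 1, 1), basis)
  p <- toy_panel(list(a = c(0, 1, -1, 2, 0), b = c(1, 1, 1, 1, 1)))
  es <- e_step(m, p)
  expect_equal(unname(es$posteriors), matrix(0.5, 2, 2))
  expect_equal(rowSums(es$posteriors), c(a = 1, b = 1))

  # K = 1: posterior identically 1
  m1 <- mixture_model(beta_same[, 1, drop = FALSE], covs[1],
                      matrix(0, 0, 1), basis)
  expect_equal(unname(e_step(m1, p)$posteriors), matrix(1, 2, 1))

  # single-visit toy against a hand Bayes computation:
  # y = 0 under N(-1,1) vs N(+1,1), equal weights -> (0.5, 0.5);
  # y = 1 -> posterior for component 2 = 1 / (1 + exp(-2))
  m_pm1 <- mixture_model(cbind(rep(-1, 4), rep(1, 4)), covs,
                         matrix(0, 1, 1), basis)
  single0 <- trajectory_panel("s", 5, 0)
  expect_equal(unname(e_step(m_pm1, single0)$posteriors),
               matrix(0.5, 1, 2))
  single1 <- trajectory_panel("s", 5, 1)
  expect_equal(unname(e_step(m_pm1, single1)$posteriors[1, 2]),
               1 / (1 + exp(-2)), tolerance = 1e-12)

  # extreme separation cannot underflow to NaN
  far <- trajectory_panel("s", 5, 1e4)
  expect_false(anyNA(e_step(m_pm1, far)$posteriors))
})

test_that("mean M-step solves the weighted GLS problem", {
  co <- simulate_cohort(default_growth_scenario(seed = 6, n_subjects = 40))
  cp <- center_trajectories(co$panel)
  basis <- build_spline_basis(cp$age)
  ids <- unique(cp$subject_id)
  # hard posteriors by true label parity; independence -> per-group OLS
  lab <- 1L + (co$true_labels[ids] %in% c(3L, 4L))
  W <- cbind(as.numeric(lab == 1L), as.numeric(lab == 2L))
  rownames(W) <- ids
  beta <- m_step_means(W, cp, basis)
  for (g in 1:2) {
    sub <- cp[cp$subject_id %in% ids[lab == g], ]
    X <- eval_basis(basis, sub$age)
    ols <- qr.solve(X, sub$value)
    expect_equal(unname(beta[, g]), unname(ols), tolerance = 1e-8)
  }
  # all-zero response gives zero coefficients
  cp0 <- cp; cp0$value <- 0
  expect_equal(unname(m_step_means(W, cp0, basis)), matrix(0, 4, 2),
               tolerance = 1e-12)
})

test_that("K = 1 mean step equals full-panel GLS under exponential covariance", {
  co <- simulate_cohort(default_growth_scenario(seed = 6, n_subjects = 40))
  cp <- center_trajectories(co$panel)
  basis <- build_spline_basis(cp$age)
  ids <- unique(cp$subject_id)
  W <- matrix(1, length(ids), 1, dimnames = list(ids, NULL))
  cov1 <- list(covariance_model("exponential", 1.4, phi = 3))
  beta <- m_step_means(W, cp, basis, cov = cov1)
  # direct GLS oracle: stack whitened per-subject blocks
  Xw <- NULL; yw <- NULL
  for (id in ids) {
    rows <- cp[cp$subject_id == id, ]
    S <- covariance_matrix(cov1[[1L]], rows$age)
    R <- solve(chol(S))
    Xw <- rbind(Xw, t(R) %*% eval_basis(basis, rows$age))
    yw <- c(yw, as.numeric(t(R) %*% rows$value))
  }
  expect_equal(as.numeric(beta), as.numeric(qr.solve(Xw, yw)),
               tolerance = 1e-8)
})

test_that("covariance M-step recovers variances and the exponential range", {
  # hard-posterior mean-square: residuals (1,-1,1,-1) around a zero curve
  p <- toy_panel(list(a = c(1, -1, 1, -1)), ages = c(2, 3.5, 5, 7))
  basis <- build_spline_basis(rep(c(2, 3.5, 5, 7, 9), 2))
  W <- matrix(1, 1, 1, dimnames = list("a", NULL))
  cm <- m_step_covariance(W, p, basis, beta = matrix(0, 4, 1),
                          kind = "independence")
  expect_equal(cm[[1L]]$sigma2, 1)

  # simulation recovery of the exponential range phi
  sc <- simulation_scenario(
    n_subjects = 1000, K_true = 1, p_visit_missing = 0,
    group_mean_curves = list(list(curve = function(t) rep(0, length(t)),
                                  base = 0)),
    level_sd = 0, noise = list(kind = "exponential", sigma = 1, phi = 3),
    seed = 17)
  co <- simulate_cohort(sc)
  ids <- unique(co$panel$subject_id)
  W1 <- matrix(1, length(ids), 1, dimnames = list(ids, NULL))
  basis5 <- build_spline_basis(co$panel$age)
  cmx <- m_step_covariance(W1, co$panel, basis5,
                           beta = matrix(0, 4, 1), kind = "exponential")
  expect_lt(abs(cmx[[1L]]$phi - 3) / 3, 0.15)
  expect_lt(abs(cmx[[1L]]$sigma2 - 1), 0.15)

  # all-zero residuals floor the variance with a warning
  p0 <- toy_panel(list(a = c(0, 0, 0, 0), b = c(0, 0, 0, 0)))
  W0 <- matrix(1, 2, 1, dimnames = list(c("a", "b"), NULL))
  expect_warning(
    cm0 <- m_step_covariance(W0, p0, basis, beta = matrix(0, 4, 1),
                             kind = "independence"),
    "floor")
  expect_equal(cm0[[1L]]$sigma2, 1e-8)
})

test_that("concomitant M-step maximizes the weighted multinomial likelihood", {
  # intercept-only symmetric posteriors -> zero coefficients
  W4 <- matrix(0.25, 40, 4)
  Z1 <- matrix(1, 40, 1, dimnames = list(NULL, "(Intercept)"))
  expect_equal(unname(m_step_concomitant(W4, Z1)), matrix(0, 3, 1))
  W2 <- matrix(0.5, 40, 2)
  expect_equal(unname(m_step_concomitant(W2, Z1)), matrix(0, 1, 1))

  # hard 0/1 posteriors with one covariate: compare to a brute-force
  # direct maximization of the multinomial log-likelihood
  set.seed(42)
  n <- 120
  z <- rnorm(n)
  pr <- 1 / (1 + exp(-(0.4 + 1.1 * z)))
  y <- rbinom(n, 1, pr)
  W <- cbind(y, 1 - y)
  Z <- cbind("(Intercept)" = 1, z = z)
  G <- m_step_concomitant(W, Z)
  nll <- function(g) {
    eta <- Z %*% g
    -sum(W[, 1] * eta - log(1 + exp(eta)))
  }
  o <- optim(c(0, 0), nll, method = "BFGS",
             control = list(reltol = 1e-14))
  expect_equal(as.numeric(G), o$par, tolerance = 1e-4)
})

test_that("three-component concomitant solver matches a brute-force maximizer", {
  # K = 3 with a covariate exercises the full block Newton system (the
  # K = 2 case degenerates to a single block)
  set.seed(4242)
  n <- 150
  z <- rnorm(n)
  G_true <- matrix(c(0.3, 1.2, -0.4, -0.8), 2, 2, byrow = TRUE)
  Z <- cbind("(Intercept)" = 1, z = z)
  eta <- cbind(Z %*% t(G_true), 0)
  P <- exp(eta - apply(eta, 1, max)); P <- P / rowSums(P)
  y <- vapply(seq_len(n), function(i) sample(3, 1, prob = P[i, ]), integer(1))
  W <- outer(y, 1:3, "==") * 1
  G <- m_step_concomitant(W, Z)
  nll <- function(th) {
    e <- cbind(Z %*% t(matrix(th, 2, 2, byrow = TRUE)), 0)
    -sum(W * (e - log(rowSums(exp(e)))))
  }
  o <- optim(rep(0, 4), nll, method = "BFGS", control = list(reltol = 1e-14))
  expect_equal(as.numeric(t(G)), o$par, tolerance = 1e-4)
})

test_that("concomitant solver stays bounded under complete separation", {
  z <- c(rep(-2, 20), rep(2, 20))
  W <- cbind(as.numeric(z > 0), as.numeric(z <= 0))
  Z <- cbind("(Intercept)" = 1, z = z)
  G <- suppressWarnings(m_step_concomitant(W, Z))
  expect_true(all(is.finite(G)))
  expect_true(all(abs(Z %*% as.numeric(G)) <= 30 + 1e-8))
})
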