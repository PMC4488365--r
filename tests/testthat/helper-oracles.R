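# Independent oracles and small fixture builders used across tests.
# These deliberately avoid the package's own computational paths.

# log multivariate normal density via base determinant/solve (not the
# package's cholesky route)
oracle_dmvnorm_log <- function(y, mu, S) {
  r <- y - mu
  m <- length(y)
  as.numeric(-0.5 * (m * log(2 * pi) + log(det(S)) +
                       t(r) %*% solve(S) %*% r))
}

# direct mixture log-likelihood by looping subjects (oracle for
# mixture_loglik and the EM maximum)
oracle_mixture_loglik <- function(panel, beta, sigma2, gamma_int, basis_fun,
                                  ages_by_subject = NULL) {
  ids <- unique(panel$subject_id)
  K <- ncol(beta)
  eta <- c(gamma_int, 0)
  logpi <- eta - log(sum(exp(eta)))
  ll <- 0
  for (id in ids) {
    rows <- panel[panel$subject_id == id, ]
    X <- basis_fun(rows$age)
    terms <- vapply(seq_len(K), function(k) {
      logpi[k] + oracle_dmvnorm_log(rows$value, as.numeric(X %*% beta[, k]),
                                    diag(sigma2[k], nrow(rows)))
    }, numeric(1))
    mx <- max(terms)
    ll <- ll + mx + log(sum(exp(terms - mx)))
  }
  ll
}

# brute-force direct maximization of the K=2 independence mixture
# likelihood over (beta, log sigma2, gamma intercept) with multiple
# random optim starts
oracle_direct_max <- function(panel, basis_fun, d, n_starts = 15L,
                              seed = 1L) {
  obj <- function(th) {
    beta <- matrix(th[1:(2 * d)], d, 2)
    sigma2 <- exp(th[2 * d + 1:2])
    -oracle_mixture_loglik(panel, beta, sigma2, th[2 * d + 3], basis_fun)
  }
  set.seed(seed)
  best <- Inf
  for (s in seq_len(n_starts)) {
    th0 <- c(stats::rnorm(2 * d, 0, 2), stats::runif(2, -1, 1),
             stats::rnorm(1, 0, 0.5))
    o <- tryCatch(stats::optim(th0, obj, method = "BFGS",
                               control = list(maxit = 500, reltol = 1e-12)),
                  error = function(e) NULL)
    if (!is.null(o) && o$value < best) best <- o$value
  }
  -best
}

# best label-agreement over all permutations of 1..K
oracle_match_accuracy <- function(labels, truth, K) {
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  truth <- truth[names(labels)]
  max(vapply(perms(seq_len(K)), function(p) mean(p[labels] == truth),
             numeric(1)))
}

# direct evaluation of the RRR probability-ratio definition at covariate z
oracle_rrr_ratio <- function(gamma, z, j, delta = 1) {
  K <- nrow(gamma) + 1L
  probs <- function(zz) {
    eta <- c(gamma %*% c(1, zz), 0)
    exp(eta) / sum(exp(eta))
  }
  p0 <- probs(z); p1 <- probs(z + delta)
  (p1[j] / p0[j]) / (p1[K] / p0[K])
}

# small deterministic panel builder
toy_panel <- function(values_by_subject, ages = c(2, 3.5, 5, 7, 9)) {
  ids <- rep(names(values_by_subject),
             vapply(values_by_subject, length, integer(1)))
  trajectory_panel(ids,
                   unlist(lapply(values_by_subject,
                                 function(v) ages[seq_along(v)])),
                   unlist(values_by_subject))
}

# a tiny three-visit two-group cohort for oracle-equivalence checks
tiny_two_group_panel <- function(seed, n = 30L) {
  set.seed(seed)
  ages <- c(2, 5, 9)
  curves <- list(function(t) 0.9 * (t - 5.4), function(t) rep(0, length(t)))
  g <- 1L + (stats::runif(n) < 0.5)
  ids <- sprintf("T%03d", seq_len(n))
  val <- unlist(lapply(seq_len(n), function(i) {
    curves[[g[i]]](ages) + stats::rnorm(3, 0, 0.5)
  }))
  list(panel = trajectory_panel(rep(ids, each = 3), rep(ages, n), val),
       truth = stats::setNames(g, ids))
}
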