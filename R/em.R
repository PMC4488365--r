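# EM machinery for the trajectory-shape mixture.
#
# Subjects are grouped by their visit-age signature ("pattern"); within a
# pattern every subject shares the basis matrix X and, per component, the
# covariance matrix, so densities and M-step accumulations are vectorised
# over subjects. With 5 nominal visits and a >= 4-visit inclusion rule there
# are at most 6 patterns, which makes E/M steps a handful of small dense
# operations per component.

LOG2PI <- log(2 * pi)
VAR_FLOOR <- 1e-8
ETA_CAP <- 30

# Group a centered panel into visit patterns aligned with a basis.
stack_panel <- function(cpanel, basis) {
  ids <- cpanel$subject_id
  subjects <- unique(ids)               # panel is sorted subject-then-age
  split_idx <- split(seq_len(nrow(cpanel)), factor(ids, levels = subjects))
  sig <- vapply(split_idx, function(ix) {
    paste(format(cpanel$age[ix], digits = 12), collapse = "|")
  }, character(1))
  patterns <- lapply(split(seq_along(subjects), sig), function(sub_pos) {
    ages <- cpanel$age[split_idx[[sub_pos[1L]]]]
    Y <- do.call(rbind, lapply(split_idx[sub_pos], function(ix) cpanel$value[ix]))
    list(ages = ages,
         X = eval_basis(basis, ages),
         D = abs(outer(ages, ages, "-")),
         Y = Y,
         idx = sub_pos)
  })
  list(subjects = subjects, patterns = patterns,
       n = length(subjects), basis = basis,
       n_records = nrow(cpanel))
}

# n x K matrix of log N(y_i ; X_i beta_k, Sigma_k(ages_i))
component_logdens <- function(stacked, beta, covs) {
  K <- ncol(beta)
  out <- matrix(NA_real_, stacked$n, K)
  for (p in stacked$patterns) {
    m <- length(p$ages)
    for (k in seq_len(K)) {
      E <- sweep(p$Y, 2L, as.numeric(p$X %*% beta[, k]))
      if (covs[[k]]$kind == "independence") {
        s2 <- covs[[k]]$sigma2
        out[p$idx, k] <- -0.5 * (m * (LOG2PI + log(s2)) + rowSums(E^2) / s2)
      } else {
        S <- covariance_matrix(covs[[k]], p$ages)
        U <- chol(S)
        logdet <- 2 * sum(log(diag(U)))
        Si <- chol2inv(U)
        Q <- rowSums((E %*% Si) * E)
        out[p$idx, k] <- -0.5 * (m * LOG2PI + logdet + Q)
      }
    }
  }
  out
}

# Align a covariate matrix to the stacked subject order; NULL means
# intercept-only. A leading "(Intercept)" column is respected, otherwise
# one is prepended.
align_covariates <- function(covariates, subjects) {
  n <- length(subjects)
  if (is.null(covariates)) {
    return(matrix(1, n, 1L, dimnames = list(subjects, "(Intercept)")))
  }
  covariates <- as.matrix(covariates)
  if (is.null(rownames(covariates))) {
    stop_trajmix("covariate matrix must have subject ids as rownames",
                 "trajmix_config_error")
  }
  missing <- setdiff(subjects, rownames(covariates))
  if (length(missing)) {
    stop_trajmix(sprintf("covariates missing for %d subject(s), e.g. %s",
                         length(missing), missing[1L]),
                 "trajmix_consistency_error")
  }
  Z <- covariates[subjects, , drop = FALSE]
  if (is.null(colnames(Z)) || colnames(Z)[1L] != "(Intercept)") {
    Z <- cbind("(Intercept)" = 1, Z)
  }
  storage.mode(Z) <- "double"
  Z
}

# log membership probabilities log pi_k(z_i); gamma is (K-1) x q with the
# reference group K carrying implicit zeros.
log_mixture_weights <- function(gamma, Z, K) {
  if (K == 1L) return(matrix(0, nrow(Z), 1L))
  eta <- cbind(Z %*% t(gamma), 0)
  eta - logsumexp_rows(eta)
}

#' Bundle mixture parameters into a model object
#'
#' @param beta matrix of spline coefficients, basis dimension x K, one
#'   column per group (centered-outcome units).
#' @param cov list of K [covariance_model()]s.
#' @param gamma concomitant multinomial-logit coefficient matrix, (K-1) rows
#'   by (1 + p) columns (intercept first), log-odds of each group versus the
#'   reference group K. For K = 1 use a 0-row matrix.
#' @param basis the [build_spline_basis()] the coefficients refer to.
#' @return a `mixture_model`.
#' @export
mixture_model <- function(beta, cov, gamma, basis) {
  beta <- as.matrix(beta)
  K <- ncol(beta)
  stopifnot(nrow(beta) == basis$dimension, length(cov) == K)
  gamma <- as.matrix(gamma)
  if (nrow(gamma) != K - 1L) {
    stop_trajmix("gamma must have K - 1 rows", "trajmix_config_error")
  }
  structure(list(K = K, beta = beta, cov = cov, gamma = gamma, basis = basis),
            class = "mixture_model")
}

#' Log-likelihood of the trajectory-shape mixture
#'
#' Sum over subjects of log sum_k pi_k(z_i) N(y_i; X_i beta_k, Sigma_k),
#' where X_i is the spline basis at subject i's visit ages. Computed in the
#' log domain (log-sum-exp), so it is finite for any valid parameters.
#'
#' @param model a [mixture_model()].
#' @param data a `centered_panel` (or any trajectory panel on the model's
#'   outcome scale).
#' @param covariates optional numeric matrix of concomitant covariates with
#'   subject ids as rownames (intercept added if absent); `NULL` for the
#'   covariate-free model.
#' @return scalar log-likelihood.
#' @export
mixture_loglik <- function(model, data, covariates = NULL) {
  stacked <- stack_panel(data, model$basis)
  Z <- align_covariates(covariates, stacked$subjects)
  if (model$K > 1L && ncol(Z) != ncol(model$gamma)) {
    stop_trajmix("covariate columns do not match gamma", "trajmix_config_error")
  }
  ld <- component_logdens(stacked, model$beta, model$cov)
  lw <- log_mixture_weights(model$gamma, Z, model$K)
  sum(logsumexp_rows(ld + lw))
}

#' E-step: posterior group probabilities
#'
#' posterior_ik is proportional to pi_k(z_i) times the component density of
#' subject i's centered trajectory; rows sum to one. Computed via
#' log-sum-exp so joint underflow cannot produce NaN.
#'
#' @inheritParams mixture_loglik
#' @return list with `posteriors` (n x K matrix, subject ids as rownames)
#'   and `loglik`.
#' @export
e_step <- function(model, data, covariates = NULL) {
  stacked <- stack_panel(data, model$basis)
  Z <- align_covariates(covariates, stacked$subjects)
  ld <- component_logdens(stacked, model$beta, model$cov)
  lw <- log_mixture_weights(model$gamma, Z, model$K)
  joint <- ld + lw
  lse <- logsumexp_rows(joint)
  post <- exp(joint - lse)
  rownames(post) <- stacked$subjects
  list(posteriors = post, loglik = sum(lse))
}

# internal E-step on pre-stacked data
e_step_stacked <- function(stacked, Z, beta, covs, gamma, K) {
  ld <- component_logdens(stacked, beta, covs)
  lw <- log_mixture_weights(gamma, Z, K)
  joint <- ld + lw
  lse <- logsumexp_rows(joint)
  list(post = exp(joint - lse), loglik = sum(lse))
}

#' M-step: group mean-curve coefficients
#'
#' Each group's spline coefficients solve the posterior-weighted generalized
#' least-squares normal equations, stacking every subject's basis rows with
#' weights posterior_ik and the group's current inverse covariance.
#'
#' @param posteriors n x K posterior matrix (rows sum to 1).
#' @param data a `centered_panel`.
#' @param basis a [build_spline_basis()].
#' @param cov list of K current [covariance_model()]s; defaults to
#'   independence with unit variance (which reduces each solve to
#'   posterior-weighted ordinary least squares).
#' @return basis dimension x K coefficient matrix.
#' @export
m_step_means <- function(posteriors, data, basis, cov = NULL) {
  stacked <- stack_panel(data, basis)
  K <- ncol(posteriors)
  if (is.null(cov)) {
    cov <- replicate(K, covariance_model("independence", 1), simplify = FALSE)
  }
  W <- posteriors[stacked$subjects, , drop = FALSE]
  m_step_means_stacked(W, stacked, cov)
}

m_step_means_stacked <- function(W, stacked, covs) {
  K <- ncol(W)
  d <- stacked$basis$dimension
  beta <- matrix(0, d, K)
  for (k in seq_len(K)) {
    wk <- W[, k]
    if (sum(wk) < 1e-10) {
      stop_trajmix(sprintf("group %d has vanishing total weight", k),
                   "trajmix_degenerate_component")
    }
    A <- matrix(0, d, d)
    b <- numeric(d)
    indep <- covs[[k]]$kind == "independence"
    for (p in stacked$patterns) {
      w <- wk[p$idx]
      # for independence the common sigma2 scales A and b equally and
      # cancels in the solve, so the identity weighting suffices
      Si <- if (indep) diag(length(p$ages)) else
        chol2inv(chol(covariance_matrix(covs[[k]], p$ages)))
      XtSi <- crossprod(p$X, Si)
      A <- A + sum(w) * (XtSi %*% p$X)
      b <- b + XtSi %*% crossprod(p$Y, w)
    }
    if (rcond(A) < 1e-12) {
      stop_trajmix(sprintf(
        "rank-deficient weighted design for group %d (basis dimension %d)",
        k, d), "trajmix_rank_deficient")
    }
    beta[, k] <- solve(A, b)
  }
  beta
}

#' M-step: within-subject covariance parameters
#'
#' Independence: the posterior-weighted mean squared residual over the
#' group's records. Exponential: profile likelihood — for each candidate
#' range phi the variance has a closed form, and phi is found by a 1-D
#' search of the profiled objective over log(phi) in \[log 0.01, log 100\].
#' Variances are floored at 1e-8; hitting the floor warns and flags the
#' result.
#'
#' @inheritParams m_step_means
#' @param beta current mean coefficients (basis dimension x K).
#' @param kind `"independence"` or `"exponential"`.
#' @return list of K [covariance_model()]s.
#' @export
m_step_covariance <- function(posteriors, data, basis, beta,
                              kind = c("independence", "exponential")) {
  kind <- match.arg(kind)
  stacked <- stack_panel(data, basis)
  W <- posteriors[stacked$subjects, , drop = FALSE]
  m_step_covariance_stacked(W, stacked, beta, kind)
}

m_step_covariance_stacked <- function(W, stacked, beta, kind, prev = NULL) {
  K <- ncol(W)
  lapply(seq_len(K), function(k) {
    wk <- W[, k]
    resid <- lapply(stacked$patterns, function(p) {
      sweep(p$Y, 2L, as.numeric(p$X %*% beta[, k]))
    })
    if (kind == "independence") {
      ss <- 0; nn <- 0
      for (j in seq_along(stacked$patterns)) {
        w <- wk[stacked$patterns[[j]]$idx]
        ss <- ss + sum(w * rowSums(resid[[j]]^2))
        nn <- nn + sum(w) * length(stacked$patterns[[j]]$ages)
      }
      s2 <- ss / nn
      if (s2 < VAR_FLOOR) {
        warning(sprintf("group %d variance hit the floor %.0e", k, VAR_FLOOR))
        s2 <- VAR_FLOOR
      }
      covariance_model("independence", s2)
    } else {
      prof <- function(logphi) {
        phi <- exp(logphi)
        tot_q <- 0; tot_logdet <- 0; N <- 0
        for (j in seq_along(stacked$patterns)) {
          p <- stacked$patterns[[j]]
          w <- wk[p$idx]
          C <- exp(-p$D / phi)
          U <- chol(C)
          Si <- chol2inv(U)
          tot_q <- tot_q + sum(w * rowSums((resid[[j]] %*% Si) * resid[[j]]))
          tot_logdet <- tot_logdet + sum(w) * 2 * sum(log(diag(U)))
          N <- N + sum(w) * length(p$ages)
        }
        s2 <- max(tot_q / N, VAR_FLOOR)
        list(obj = -0.5 * (N * log(s2) + tot_logdet + N), sigma2 = s2)
      }
      opt <- stats::optimize(function(lp) prof(lp)$obj,
                             interval = log(c(0.01, 100)),
                             maximum = TRUE, tol = 1e-3)
      cand_lp <- opt$maximum
      cand_obj <- opt$objective
      # keep the previous phi if the 1-D search did not improve on it, so
      # the EM objective can never decrease through this step
      if (!is.null(prev) && !is.null(prev[[k]]$phi)) {
        prev_lp <- log(prev[[k]]$phi)
        prev_obj <- prof(prev_lp)$obj
        if (prev_obj > cand_obj) {
          cand_lp <- prev_lp
        }
      }
      res <- prof(cand_lp)
      if (res$sigma2 <= VAR_FLOOR) {
        warning(sprintf("group %d variance hit the floor %.0e", k, VAR_FLOOR))
      }
      covariance_model("exponential", res$sigma2, phi = exp(cand_lp))
    }
  })
}

#' M-step: concomitant multinomial-logit coefficients
#'
#' Maximizes the posterior-weighted multinomial log-likelihood
#' sum_i sum_k posterior_ik log pi_k(z_i) over gamma. With an intercept-only
#' design the solution is closed form, gamma_k0 = log(mean posterior_k /
#' mean posterior_K); otherwise Newton iterations with step-halving are
#' used. Linear predictors are capped at |eta| <= 30: if a step would
#' exceed the cap (separation), a warning is issued and the capped
#' coefficients returned.
#'
#' @param posteriors n x K posterior matrix.
#' @param covariates design matrix with intercept first (n x q), rows
#'   aligned with `posteriors`.
#' @param gamma_init optional (K-1) x q warm start.
#' @return (K-1) x q coefficient matrix (columns named after the design).
#' @export
m_step_concomitant <- function(posteriors, covariates, gamma_init = NULL) {
  W <- as.matrix(posteriors)
  K <- ncol(W)
  Z <- as.matrix(covariates)
  q <- ncol(Z)
  cn <- colnames(Z) %||% c("(Intercept)", paste0("z", seq_len(q - 1L)))
  if (K == 1L) {
    return(matrix(0, 0L, q, dimnames = list(NULL, cn)))
  }
  if (q == 1L) {
    pbar <- pmax(colMeans(W), 1e-12)
    g <- log(pbar[seq_len(K - 1L)] / pbar[K])
    g <- pmin(pmax(g, -ETA_CAP), ETA_CAP)
    return(matrix(g, K - 1L, 1L, dimnames = list(NULL, cn)))
  }
  G <- if (is.null(gamma_init)) matrix(0, K - 1L, q) else as.matrix(gamma_init)
  ll_of <- function(G) {
    eta <- cbind(Z %*% t(G), 0)
    sum(W * (eta - logsumexp_rows(eta)))
  }
  ll <- ll_of(G)
  for (iter in seq_len(100L)) {
    eta <- cbind(Z %*% t(G), 0)
    P <- softmax_rows(eta)
    grad <- as.numeric(vapply(seq_len(K - 1L),
                              function(k) crossprod(Z, W[, k] - P[, k]),
                              numeric(q)))
    if (max(abs(grad)) < 1e-9) break
    H <- matrix(0, (K - 1L) * q, (K - 1L) * q)
    for (k in seq_len(K - 1L)) {
      for (l in k:(K - 1L)) {
        wkl <- P[, k] * ((k == l) - P[, l])
        blk <- crossprod(Z, Z * wkl)
        ri <- (k - 1L) * q + seq_len(q)
        ci <- (l - 1L) * q + seq_len(q)
        H[ri, ci] <- blk
        H[ci, ri] <- t(blk)
      }
    }
    step <- tryCatch(solve(H + diag(1e-10, nrow(H)), grad),
                     error = function(e) grad / max(1, max(abs(grad))))
    accepted <- FALSE
    for (h in 0:30) {
      # step is stacked in k-major blocks of length q, matching the
      # Hessian block layout, so it maps onto rows of G
      Gn <- G + matrix(step, K - 1L, q, byrow = TRUE) * 2^(-h)
      eta_n <- Z %*% t(Gn)
      if (max(abs(eta_n)) > ETA_CAP) next
      ll_n <- ll_of(Gn)
      if (ll_n >= ll - 1e-12) {
        G <- Gn
        improved <- ll_n - ll
        ll <- ll_n
        accepted <- TRUE
        break
      }
    }
    if (!accepted || improved < 1e-11) break
  }
  if (max(abs(Z %*% t(G))) >= ETA_CAP - 1e-6) {
    warning("separation in concomitant model: linear predictor capped at |eta| <= 30")
  }
  dimnames(G) <- list(NULL, cn)
  G
}

# one ECM sweep + E-step from responsibilities W; returns updated state
em_iterate <- function(W, stacked, Z, kind, covs, gamma, K) {
  beta <- m_step_means_stacked(W, stacked, covs)
  covs <- m_step_covariance_stacked(W, stacked, beta, kind, prev = covs)
  gamma <- if (K > 1L) {
    m_step_concomitant(W, Z, gamma_init = gamma)
  } else {
    matrix(0, 0L, ncol(Z), dimnames = list(NULL, colnames(Z)))
  }
  es <- e_step_stacked(stacked, Z, beta, covs, gamma, K)
  list(W = es$post, loglik = es$loglik, beta = beta, covs = covs,
       gamma = gamma)
}

run_em <- function(W0, stacked, Z, K, kind, max_iter, tol,
                   init_covs = NULL, init_gamma = NULL) {
  if (is.null(init_covs)) {
    init_s2 <- max(stats::var(unlist(lapply(stacked$patterns,
                                            function(p) as.numeric(p$Y)))),
                   VAR_FLOOR)
    init_covs <- replicate(K, {
      if (kind == "independence") covariance_model("independence", init_s2)
      else covariance_model("exponential", init_s2, phi = 2)
    }, simplify = FALSE)
  }
  covs <- init_covs
  gamma <- init_gamma
  W <- W0
  trace <- numeric(0)
  converged <- FALSE
  st <- NULL
  for (iter in seq_len(max_iter)) {
    st <- em_iterate(W, stacked, Z, kind, covs, gamma, K)
    W <- st$W; covs <- st$covs; gamma <- st$gamma
    trace <- c(trace, st$loglik)
    if (iter > 1L) {
      prev <- trace[iter - 1L]
      if (abs(st$loglik - prev) <= tol * (abs(prev) + 1e-3)) {
        converged <- TRUE
        break
      }
    }
  }
  list(W = W, beta = st$beta, covs = covs, gamma = st$gamma,
       loglik = trace[length(trace)], trace = trace, converged = converged)
}

# deterministic k-means-style start: subjects x distinct-age matrix of
# centered values with column-mean imputation for missing visits
kmeans_start <- function(stacked, cpanel, K) {
  ages_all <- sort(unique(cpanel$age))
  M <- matrix(NA_real_, stacked$n, length(ages_all))
  for (p in stacked$patterns) {
    cols <- match(p$ages, ages_all)
    M[p$idx, cols] <- p$Y
  }
  for (j in seq_len(ncol(M))) {
    mj <- mean(M[, j], na.rm = TRUE)
    M[is.na(M[, j]), j] <- if (is.finite(mj)) mj else 0
  }
  km <- tryCatch(stats::kmeans(M, centers = K, nstart = 5L, iter.max = 50L),
                 error = function(e) NULL)
  W <- matrix(1e-3, stacked$n, K)
  if (is.null(km)) {
    cl <- rep_len(seq_len(K), stacked$n)
  } else {
    cl <- km$cluster
  }
  W[cbind(seq_len(stacked$n), cl)] <- 1
  W / rowSums(W)
}

random_start <- function(n, K) {
  W <- matrix(stats::rgamma(n * K, shape = 1), n, K)
  W / rowSums(W)
}

#' Fit the trajectory-shape mixture by multi-start EM
#'
#' Alternates the E-step with conditional M-steps for the group mean-curve
#' coefficients (weighted GLS), the covariance parameters, and the
#' concomitant multinomial coefficients until the relative log-likelihood
#' change falls below `tol`. `n_starts` initializations are used: one
#' deterministic k-means partition of visit-aligned centered vectors (with
#' mean imputation for missing visits) and the remainder random soft
#' assignments. Every start is run for a short screening phase and the best
#' is continued to convergence. Groups are relabeled by the fitted mean
#' curve value at the maximum observed age, in decreasing order, so group 1
#' is the steepest riser and group K the flattest.
#'
#' @param data a `centered_panel` (see [center_trajectories()]).
#' @param covariates optional concomitant covariate matrix (subject ids as
#'   rownames); `NULL` fits the covariate-free model.
#' @param K number of groups (>= 1).
#' @param cov_kind `"independence"` or `"exponential"`.
#' @param n_starts number of initializations (default 20).
#' @param max_iter EM iteration cap (default 500).
#' @param tol relative log-likelihood convergence tolerance (default 1e-8).
#' @param seed integer seed governing all random starts.
#' @param basis optional [build_spline_basis()]; by default quadratic with
#'   one internal knot at the pooled median observed age of `data`.
#' @param init_posteriors optional list of n x K posterior matrices
#'   (subject ids as rownames) used as additional warm starts.
#' @param burn_iter iterations per start in the screening phase (default 15).
#' @return a `traj_fit`: list with `model` ([mixture_model()]), `loglik`,
#'   `bic`, `n_subjects`, `n_params`, `posteriors`, `labels`, `converged`,
#'   `n_iter`, `trace`, plus the data/covariates needed to recompute the
#'   likelihood (used for Wald standard errors).
#' @export
fit_em <- function(data, covariates = NULL, K, cov_kind = "independence",
                   n_starts = 20L, max_iter = 500L, tol = 1e-8, seed = 1L,
                   basis = NULL, init_posteriors = NULL, burn_iter = 15L) {
  stopifnot(K >= 1L)
  cov_kind <- match.arg(cov_kind, c("independence", "exponential"))
  if (is.null(basis)) {
    basis <- build_spline_basis(data$age)
  }
  stacked <- stack_panel(data, basis)
  if (stacked$n < K) {
    stop_trajmix("fewer subjects than groups", "trajmix_config_error")
  }
  Z <- align_covariates(covariates, stacked$subjects)
  q <- ncol(Z)

  if (K == 1L) {
    run <- run_em(matrix(1, stacked$n, 1L), stacked, Z, 1L, cov_kind,
                  max_iter, tol)
    best <- run
    trace <- run$trace
  } else {
    set.seed(seed)
    starts <- list(kmeans_start(stacked, data, K))
    if (!is.null(init_posteriors)) {
      for (P0 in init_posteriors) {
        P0 <- as.matrix(P0)
        if (is.null(rownames(P0)) || ncol(P0) != K) {
          stop_trajmix("init_posteriors must be n x K with subject rownames",
                       "trajmix_config_error")
        }
        starts <- c(starts, list(pmax(P0[stacked$subjects, , drop = FALSE],
                                      1e-8)))
      }
    }
    while (length(starts) < n_starts) {
      starts <- c(starts, list(random_start(stacked$n, K)))
    }
    burns <- vector("list", length(starts))
    for (s in seq_along(starts)) {
      burns[[s]] <- tryCatch(
        suppressWarnings(run_em(starts[[s]], stacked, Z, K, cov_kind,
                                burn_iter, tol)),
        error = function(e) NULL)
    }
    ok <- !vapply(burns, is.null, logical(1))
    if (!any(ok)) {
      stop_trajmix("no EM start converged past the screening phase",
                   "trajmix_nonconvergence")
    }
    lls <- vapply(burns, function(b) if (is.null(b)) -Inf else b$loglik,
                  numeric(1))
    champ <- burns[[which.max(lls)]]
    if (champ$converged) {
      best <- champ
      trace <- champ$trace
    } else {
      # continue the champion from its own state so the joined trace
      # remains a single monotone EM trajectory
      cont <- run_em(champ$W, stacked, Z, K, cov_kind, max_iter, tol,
                     init_covs = champ$covs, init_gamma = champ$gamma)
      best <- cont
      trace <- c(champ$trace, cont$trace)
    }
  }

  # resolve label switching: order groups by fitted curve value at the
  # maximum observed age, descending (group 1 = steepest riser)
  t_max <- max(data$age)
  x_max <- eval_basis(basis, t_max)
  curve_at_max <- as.numeric(x_max %*% best$beta)
  ord <- order(curve_at_max, decreasing = TRUE)
  beta <- best$beta[, ord, drop = FALSE]
  covs <- best$covs[ord]
  W <- best$W[, ord, drop = FALSE]
  if (K > 1L) {
    Gfull <- rbind(best$gamma, 0)[ord, , drop = FALSE]
    gamma <- sweep(Gfull[seq_len(K - 1L), , drop = FALSE], 2L,
                   Gfull[K, ], "-")
    colnames(gamma) <- colnames(Z)
  } else {
    gamma <- matrix(0, 0L, q, dimnames = list(NULL, colnames(Z)))
  }
  rownames(W) <- stacked$subjects
  labels <- max.col(W, ties.method = "first")
  names(labels) <- stacked$subjects

  n_cov_par <- if (cov_kind == "independence") 1L else 2L
  n_params <- K * basis$dimension + K * n_cov_par + (K - 1L) * q
  model <- mixture_model(beta, covs, gamma, basis)
  fit <- structure(list(
    model = model,
    loglik = best$loglik,
    n_subjects = stacked$n,
    n_params = n_params,
    posteriors = W,
    labels = labels,
    converged = best$converged,
    n_iter = length(trace),
    trace = trace,
    cov_kind = cov_kind,
    covariate_names = colnames(Z),
    data = as.data.frame(data),
    subject_means = attr(data, "subject_means"),
    Z = Z,
    seed = seed
  ), class = "traj_fit")
  fit$bic <- bic(fit)
  fit
}

#' @export
print.traj_fit <- function(x, ...) {
  cat(sprintf(
    "<traj_fit> K = %d (%s covariance), n = %d subjects\n  loglik = %.4f, BIC = %.4f, %d parameters, %s in %d iterations\n",
    x$model$K, x$cov_kind, x$n_subjects, x$loglik, x$bic, x$n_params,
    if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}
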