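#' Bayesian Information Criterion of a mixture fit
#'
#' BIC = -2 loglik + d log(n), with n the number of subjects (the mixture's
#' independent units) and d the parameter count: K spline coefficient
#' vectors, K covariance parameter sets (1 for independence, 2 for
#' exponential) and (K-1)(1+p) concomitant coefficients.
#'
#' @param fit a `traj_fit`.
#' @return scalar BIC; smaller is better.
#' @export
bic <- function(fit) {
  -2 * fit$loglik + fit$n_params * log(fit$n_subjects)
}

#' Select the number of groups and covariance structure by BIC
#'
#' Fits the covariate-free mixture over a grid of group counts and
#' covariance structures and returns the minimum-BIC fit together with the
#' full selection table. Non-convergent cells are recorded in the table,
#' excluded from the argmin, and warned about.
#'
#' @param data a `centered_panel`.
#' @param K_range candidate group counts (default 2:5).
#' @param cov_kinds candidate covariance structures (default both).
#' @param n_starts,max_iter,tol,burn_iter passed to [fit_em()].
#' @param seed integer; each grid cell gets a deterministic seed derived
#'   from it, so the whole selection is reproducible.
#' @return a `model_selection`: list with `fit` (best), `table`
#'   (data.frame K, cov_kind, loglik, n_params, bic, converged) and `fits`
#'   (all fitted cells, named "K=k,kind").
#' @export
select_model <- function(data, K_range = 2:5,
                         cov_kinds = c("independence", "exponential"),
                         n_starts = 20L, max_iter = 500L, tol = 1e-8,
                         seed = 1L, burn_iter = 15L) {
  grid <- expand.grid(K = K_range, cov_kind = cov_kinds,
                      stringsAsFactors = FALSE)
  fits <- vector("list", nrow(grid))
  names(fits) <- paste0("K=", grid$K, ",", grid$cov_kind)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cell_seed <- (seed + 97L * i) %% .Machine$integer.max
    f <- tryCatch(
      suppressWarnings(fit_em(data, covariates = NULL, K = grid$K[i],
                              cov_kind = grid$cov_kind[i],
                              n_starts = n_starts, max_iter = max_iter,
                              tol = tol, seed = cell_seed,
                              burn_iter = burn_iter)),
      error = function(e) e)
    if (inherits(f, "error")) {
      warning(sprintf("cell K=%d %s failed: %s", grid$K[i], grid$cov_kind[i],
                      conditionMessage(f)))
      rows[[i]] <- data.frame(K = grid$K[i], cov_kind = grid$cov_kind[i],
                              loglik = NA_real_, n_params = NA_integer_,
                              bic = NA_real_, converged = FALSE)
    } else {
      fits[[i]] <- f
      rows[[i]] <- data.frame(K = grid$K[i], cov_kind = grid$cov_kind[i],
                              loglik = f$loglik, n_params = f$n_params,
                              bic = f$bic, converged = f$converged)
    }
  }
  tab <- do.call(rbind, rows)
  eligible <- which(tab$converged & is.finite(tab$bic))
  if (!length(eligible)) {
    stop_trajmix("no model-selection cell converged", "trajmix_nonconvergence")
  }
  best_i <- eligible[which.min(tab$bic[eligible])]
  structure(list(fit = fits[[best_i]], table = tab, fits = fits),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat("<model_selection> BIC grid:\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("selected: K = %d, %s covariance (BIC = %.2f)\n",
              x$fit$model$K, x$fit$cov_kind, x$fit$bic))
  invisible(x)
}

#' Posterior classification and uncertainty summary
#'
#' Subjects are assigned to the group with the largest posterior
#' probability (ties broken toward the lowest group index). The uncertainty
#' summary reports, per group, the fraction of that group's posterior
#' probabilities lying strictly between 0.1 and 0.9 — values near 0/1
#' indicate confident memberships, values near 0.5 a trajectory in between
#' two groups.
#'
#' @param fit a `traj_fit`.
#' @return list with `labels` (named integer vector) and `uncertainty`
#'   (data.frame group, frac_between_0.1_0.9).
#' @export
classify <- function(fit) {
  post <- fit$posteriors
  labels <- max.col(post, ties.method = "first")
  names(labels) <- rownames(post)
  unc <- data.frame(
    group = seq_len(ncol(post)),
    frac_between_0.1_0.9 = vapply(seq_len(ncol(post)), function(g) {
      mean(post[, g] > 0.1 & post[, g] < 0.9)
    }, numeric(1)))
  list(labels = labels, uncertainty = unc)
}

#' Fitted group mean curves on a dense age grid
#'
#' @param fit a `traj_fit`.
#' @param ages age grid; defaults to 101 points spanning the basis boundary.
#' @return data.frame (age, group, value) of centered-scale mean curves,
#'   suitable for plotting.
#' @export
group_curves <- function(fit, ages = NULL) {
  basis <- fit$model$basis
  if (is.null(ages)) {
    ages <- seq(basis$boundary_knots[1L], basis$boundary_knots[2L],
                length.out = 101L)
  }
  X <- eval_basis(basis, ages)
  M <- X %*% fit$model$beta
  data.frame(age = rep(ages, times = ncol(M)),
             group = rep(seq_len(ncol(M)), each = length(ages)),
             value = as.numeric(M))
}
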