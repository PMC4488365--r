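#' Build a concomitant covariate design
#'
#' Assembles the multinomial-logit design for group membership: an
#' intercept, exposure column(s), confounders, and optional exposure x
#' modifier interaction columns. Subjects with a missing value in any used
#' column are dropped (complete case); the count is recorded in the
#' `dropped_subjects` attribute. The design must have full column rank on
#' the analysis subjects.
#'
#' @param baseline a `baseline_table`.
#' @param exposures character vector of exposure column names.
#' @param confounders character vector of confounder column names.
#' @param interactions optional list of `c(exposure, modifier)` pairs; each
#'   adds a product column named `"exposure:modifier"`.
#' @return numeric matrix (intercept first) with subject ids as rownames,
#'   class `concomitant_design`; attributes `exposures`, `confounders`,
#'   `dropped_subjects`.
#' @export
concomitant_design <- function(baseline, exposures, confounders = character(),
                               interactions = NULL) {
  vars <- c(exposures, confounders)
  unknown <- setdiff(vars, names(baseline))
  if (length(unknown)) {
    stop_trajmix(sprintf("unknown covariate(s): %s",
                         paste(unknown, collapse = ", ")),
                 "trajmix_config_error")
  }
  M <- as.matrix(baseline[vars])
  storage.mode(M) <- "double"
  if (!is.null(interactions)) {
    for (pair in interactions) {
      stopifnot(length(pair) == 2L)
      if (!all(pair %in% names(baseline))) {
        stop_trajmix(sprintf("unknown interaction variable in %s",
                             paste(pair, collapse = ":")),
                     "trajmix_config_error")
      }
      M <- cbind(M, as.numeric(baseline[[pair[1L]]]) *
                    as.numeric(baseline[[pair[2L]]]))
      colnames(M)[ncol(M)] <- paste(pair, collapse = ":")
    }
  }
  complete <- stats::complete.cases(M)
  dropped <- baseline$subject_id[!complete]
  if (length(dropped)) {
    message(sprintf("complete-case analysis: dropping %d of %d subjects with missing covariates",
                    length(dropped), nrow(baseline)))
  }
  M <- M[complete, , drop = FALSE]
  Z <- cbind("(Intercept)" = 1, M)
  rownames(Z) <- baseline$subject_id[complete]
  if (qr(Z)$rank < ncol(Z)) {
    stop_trajmix("concomitant design is rank deficient",
                 "trajmix_rank_deficient")
  }
  structure(Z, class = c("concomitant_design", "matrix"),
            exposures = exposures, confounders = confounders,
            dropped_subjects = dropped)
}

#' Re-estimate the full mixture with concomitant covariates
#'
#' After the number of groups and covariance structure have been chosen on
#' the covariate-free model, baseline risk factors enter the group
#' membership probabilities and the whole mixture (mean curves, covariance
#' parameters and concomitant coefficients) is jointly re-estimated. The
#' EM is warm-started from the covariate-free fit's posteriors, plus random
#' restarts.
#'
#' @param data a `centered_panel`.
#' @param design a [concomitant_design()] (its rownames define the analysis
#'   subjects; the panel is subset to them).
#' @param K,cov_kind the selected number of groups and covariance
#'   structure.
#' @param seed integer seed for the random restarts.
#' @param base_fit optional covariate-free `traj_fit` whose posteriors warm
#'   start the EM.
#' @param n_starts total initializations (default 5).
#' @param ... passed to [fit_em()].
#' @return a `traj_fit` whose model's `gamma` is (K-1) x (1 + p).
#' @export
refit_with_covariates <- function(data, design, K, cov_kind, seed = 1L,
                                  base_fit = NULL, n_starts = 5L, ...) {
  subjects <- rownames(design)
  sub <- data[data$subject_id %in% subjects, , drop = FALSE]
  attr(sub, "subject_means") <-
    attr(data, "subject_means")[intersect(names(attr(data, "subject_means")),
                                          unique(sub$subject_id))]
  class(sub) <- class(data)
  inits <- NULL
  if (!is.null(base_fit)) {
    P0 <- base_fit$posteriors
    common <- intersect(rownames(P0), unique(sub$subject_id))
    if (length(common)) {
      inits <- list(P0[common, , drop = FALSE])
    }
  }
  fit_em(sub, covariates = design, K = K, cov_kind = cov_kind,
         n_starts = n_starts, seed = seed, init_posteriors = inits, ...)
}

#' Relative risk ratios for a concomitant covariate
#'
#' Under the multinomial-logit membership model the relative risk ratio for
#' group j versus the reference group K under a `delta`-unit covariate
#' increase,
#' \[P(j | z + delta) / P(j | z)\] / \[P(K | z + delta) / P(K | z)\],
#' does not depend on z and equals exp(delta * gamma_j).
#'
#' @param fit a `traj_fit` from [refit_with_covariates()].
#' @param covariate covariate name.
#' @param delta covariate increment (default 1; with log10 exposures one
#'   unit is a ten-fold concentration increase).
#' @return named numeric vector of RRRs for groups 1..K-1.
#' @export
rrr <- function(fit, covariate, delta = 1) {
  g <- fit$model$gamma
  if (!covariate %in% colnames(g)) {
    stop_trajmix(sprintf("covariate '%s' not in the concomitant design",
                         covariate), "trajmix_lookup_error")
  }
  stats::setNames(exp(delta * g[, covariate]),
                  paste0("group", seq_len(nrow(g))))
}

# ---- parameter packing for the observed information ------------------------

pack_params <- function(model, cov_kind) {
  th <- as.numeric(model$beta)
  for (k in seq_len(model$K)) {
    th <- c(th, model$cov[[k]]$sigma2,
            if (cov_kind == "exponential") model$cov[[k]]$phi)
  }
  c(th, as.numeric(t(model$gamma)))
}

unpack_params <- function(theta, template, cov_kind) {
  K <- template$K
  d <- template$basis$dimension
  q <- ncol(template$gamma)
  beta <- matrix(theta[seq_len(K * d)], d, K)
  pos <- K * d
  ncv <- if (cov_kind == "exponential") 2L else 1L
  covs <- vector("list", K)
  for (k in seq_len(K)) {
    s2 <- theta[pos + 1L]
    if (cov_kind == "exponential") {
      covs[[k]] <- covariance_model("exponential", s2, phi = theta[pos + 2L])
    } else {
      covs[[k]] <- covariance_model("independence", s2)
    }
    pos <- pos + ncv
  }
  ng <- (K - 1L) * q
  gamma <- matrix(theta[pos + seq_len(ng)], K - 1L, q, byrow = TRUE,
                  dimnames = dimnames(template$gamma))
  mixture_model(beta, covs, gamma, template$basis)
}

# observed information of the full mixture log-likelihood at the fit,
# by central-difference numerical differentiation (step h on the natural
# scale of every parameter)
observed_information <- function(fit, h = 1e-4) {
  model <- fit$model
  stacked <- stack_panel(fit$data, model$basis)
  Z <- fit$Z
  theta <- pack_params(model, fit$cov_kind)
  d <- length(theta)
  f <- function(th) {
    m <- unpack_params(th, model, fit$cov_kind)
    ld <- component_logdens(stacked, m$beta, m$cov)
    lw <- log_mixture_weights(m$gamma, Z, m$K)
    sum(logsumexp_rows(ld + lw))
  }
  f0 <- f(theta)
  H <- matrix(NA_real_, d, d)
  fp <- numeric(d); fm <- numeric(d)
  for (i in seq_len(d)) {
    ei <- replace(numeric(d), i, h)
    fp[i] <- f(theta + ei)
    fm[i] <- f(theta - ei)
    H[i, i] <- (fp[i] - 2 * f0 + fm[i]) / h^2
  }
  if (d > 1L) {
    for (i in seq_len(d - 1L)) {
      for (j in (i + 1L):d) {
        ei <- replace(numeric(d), i, h)
        ej <- replace(numeric(d), j, h)
        H[i, j] <- H[j, i] <-
          (f(theta + ei + ej) - f(theta + ei - ej) -
             f(theta - ei + ej) + f(theta - ei - ej)) / (4 * h^2)
      }
    }
  }
  -H
}

# indices of gamma entries within the packed parameter vector
gamma_indices <- function(fit) {
  K <- fit$model$K
  d <- fit$model$basis$dimension
  q <- ncol(fit$model$gamma)
  ncv <- if (fit$cov_kind == "exponential") 2L else 1L
  offset <- K * d + K * ncv
  matrix(offset + seq_len((K - 1L) * q), K - 1L, q, byrow = TRUE)
}

#' Wald confidence intervals for relative risk ratios
#'
#' Standard errors come from the inverse observed information of the *full*
#' mixture log-likelihood at the MLE (numerical central differences), so
#' classification uncertainty propagates into the intervals; the CI is
#' exp(delta * (gamma +/- z * SE)), symmetric on the log scale. A cheaper
#' two-stage variant (`method = "two_stage"`) conditions on the fitted
#' posteriors and uses the posterior-weighted multinomial information only.
#'
#' @param fit a `traj_fit` with covariates.
#' @param covariate covariate name.
#' @param level confidence level (default 0.95).
#' @param delta covariate increment for the reported RRR scale (default 1).
#' @param method `"full"` (default) or `"two_stage"`.
#' @param h central-difference step for the full-model Hessian.
#' @return data.frame (group, rrr, ci_low, ci_high, se_log, p_value).
#' @export
wald_ci <- function(fit, covariate, level = 0.95, delta = 1,
                    method = c("full", "two_stage"), h = 1e-4) {
  method <- match.arg(method)
  g <- fit$model$gamma
  if (!covariate %in% colnames(g)) {
    stop_trajmix(sprintf("covariate '%s' not in the concomitant design",
                         covariate), "trajmix_lookup_error")
  }
  K <- fit$model$K
  col <- match(covariate, colnames(g))
  if (method == "full") {
    info <- observed_information(fit, h = h)
    V <- tryCatch(solve(info), error = function(e) {
      stop_trajmix(
        "observed information is not invertible; the fit may be on the boundary or degenerate",
        "trajmix_information_error")
    })
    gi <- gamma_indices(fit)
    se <- sqrt(pmax(diag(V)[gi[, col]], 0))
  } else {
    # posterior-weighted multinomial information, gamma block only
    W <- fit$posteriors
    Z <- fit$Z
    q <- ncol(Z)
    eta <- cbind(Z %*% t(g), 0)
    P <- softmax_rows(eta)
    Hm <- matrix(0, (K - 1L) * q, (K - 1L) * q)
    for (k in seq_len(K - 1L)) {
      for (l in k:(K - 1L)) {
        wkl <- P[, k] * ((k == l) - P[, l])
        blk <- crossprod(Z, Z * wkl)
        ri <- (k - 1L) * q + seq_len(q)
        ci <- (l - 1L) * q + seq_len(q)
        Hm[ri, ci] <- blk
        Hm[ci, ri] <- t(blk)
      }
    }
    V <- solve(Hm)
    idx <- (seq_len(K - 1L) - 1L) * q + col
    se <- sqrt(pmax(diag(V)[idx], 0))
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- g[, col]
  data.frame(group = seq_len(K - 1L),
             rrr = exp(delta * est),
             ci_low = exp(delta * est - z * abs(delta) * se),
             ci_high = exp(delta * est + z * abs(delta) * se),
             se_log = se,
             p_value = 2 * stats::pnorm(-abs(ifelse(se > 0, est / se, Inf))))
}

#' Adjusted and unadjusted relative risk ratio table
#'
#' For each exposure, each sex stratum and each adjustment state
#' (exposure-only versus exposure plus the confounder set) the full mixture
#' is re-estimated with the covariates in the concomitant model and RRRs
#' with Wald CIs are computed for groups 1..K-1 versus the reference group
#' K. Exposures enter one model at a time.
#'
#' @param panel a raw `trajectory_panel` (centering happens per stratum).
#' @param baseline a `baseline_table`.
#' @param exposures character vector of exposure column names (already on
#'   the analysis scale, e.g. log10).
#' @param confounders character vector of confounder column names.
#' @param K,cov_kind selected number of groups and covariance structure.
#' @param seed integer seed.
#' @param stratify_sex fit per sex (default TRUE); if FALSE a single
#'   stratum labeled `all` is used.
#' @param delta covariate increment for the RRR scale (default 1).
#' @param base_fits optional named list of covariate-free `traj_fit`s per
#'   stratum used as warm starts.
#' @param ci_method passed to [wald_ci()].
#' @param ... passed to [refit_with_covariates()].
#' @return data.frame (sex, exposure, group, rrr, ci_low, ci_high,
#'   p_value, adjusted), K-1 rows per exposure/stratum/adjustment state.
#' @export
adjusted_and_unadjusted <- function(panel, baseline, exposures, confounders,
                                    K, cov_kind = "independence", seed = 1L,
                                    stratify_sex = TRUE, delta = 1,
                                    base_fits = NULL,
                                    ci_method = "full", ...) {
  strata <- if (stratify_sex) {
    stratify(panel, baseline, by = "sex")
  } else {
    list(all = list(panel = panel, baseline = baseline))
  }
  out <- list()
  si <- 0L
  for (sname in names(strata)) {
    st <- strata[[sname]]
    cpanel <- center_trajectories(st$panel)
    base_fit <- if (!is.null(base_fits)) base_fits[[sname]] else NULL
    for (expo in exposures) {
      for (adjusted in c(FALSE, TRUE)) {
        si <- si + 1L
        des <- concomitant_design(st$baseline, exposures = expo,
                                  confounders = if (adjusted) confounders
                                                else character())
        f <- refit_with_covariates(cpanel, des, K = K, cov_kind = cov_kind,
                                   seed = seed + 31L * si,
                                   base_fit = base_fit, ...)
        ci <- wald_ci(f, expo, delta = delta, method = ci_method)
        out[[length(out) + 1L]] <- data.frame(
          sex = sname, exposure = expo, group = ci$group,
          rrr = ci$rrr, ci_low = ci$ci_low, ci_high = ci$ci_high,
          p_value = ci$p_value, adjusted = adjusted)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Scan exposure-by-modifier interactions one at a time
#'
#' For each modifier, refits the mixture with the exposure, the modifier
#' and their product in the concomitant model, and compares it with the
#' corresponding no-interaction model: per-group interaction coefficient,
#' Wald statistic and p-value, plus the BIC of both models.
#'
#' @param panel a `trajectory_panel` (one stratum).
#' @param baseline matching `baseline_table`.
#' @param exposure the main risk factor column name.
#' @param modifiers character vector of candidate modifier column names.
#' @param K,cov_kind selected model structure.
#' @param seed integer seed.
#' @param ci_method passed to [wald_ci()].
#' @param ... passed to [refit_with_covariates()].
#' @return data.frame (modifier, group, gamma_interaction, se, wald_z,
#'   p_value, bic_base, bic_interaction); K-1 rows per modifier.
#' @export
interaction_scan <- function(panel, baseline, exposure, modifiers,
                             K, cov_kind = "independence", seed = 1L,
                             ci_method = "full", ...) {
  cpanel <- center_trajectories(panel)
  out <- list()
  for (im in seq_along(modifiers)) {
    mod <- modifiers[im]
    des0 <- concomitant_design(baseline, exposures = exposure,
                               confounders = mod)
    des1 <- concomitant_design(baseline, exposures = exposure,
                               confounders = mod,
                               interactions = list(c(exposure, mod)))
    f0 <- refit_with_covariates(cpanel, des0, K = K, cov_kind = cov_kind,
                                seed = seed + 13L * im, ...)
    f1 <- refit_with_covariates(cpanel, des1, K = K, cov_kind = cov_kind,
                                seed = seed + 13L * im + 7L,
                                base_fit = f0, ...)
    term <- paste(exposure, mod, sep = ":")
    ci <- wald_ci(f1, term, method = ci_method)
    g <- f1$model$gamma[, term]
    out[[im]] <- data.frame(
      modifier = mod, group = ci$group,
      gamma_interaction = g, se = ci$se_log,
      wald_z = ifelse(ci$se_log > 0, g / ci$se_log, Inf),
      p_value = ci$p_value,
      bic_base = f0$bic, bic_interaction = f1$bic)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
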