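#' Define a synthetic-cohort simulation scenario
#'
#' Encodes the generative model the analysis assumes: each subject draws
#' baseline covariates, a latent trajectory group via a multinomial-logit
#' concomitant model, a Normal subject-level vertical offset (level
#' heterogeneity, which the centering transformation is designed to
#' remove), and within-subject noise that is independent or exponentially
#' correlated across visits. Visits are dropped at random subject to a
#' minimum-retained-visits floor mirroring the cohort inclusion rule.
#'
#' @param n_subjects number of subjects.
#' @param visit_ages nominal visit ages in years (default 2, 3.5, 5, 7, 9).
#' @param p_visit_missing probability each single visit is dropped.
#' @param K_true number of trajectory groups.
#' @param group_mean_curves list of `K_true` entries, each
#'   `list(curve = function(age), base = <raw-scale level>)`; `curve` is the
#'   group mean on the centered scale.
#' @param level_sd SD of the subject-specific vertical offset (outcome
#'   units).
#' @param noise list `list(kind = "independence"|"exponential", sigma = ,
#'   phi = )` for the within-subject noise.
#' @param concomitant (K_true - 1) x (1 + p) coefficient matrix, columns
#'   named `(Intercept)` then covariate names, log-odds of groups 1..K-1
#'   versus the reference group K.
#' @param covariate_dist function(n) returning an n-row data.frame of
#'   baseline covariates; must contain a `sex` column and every covariate
#'   named in `concomitant`.
#' @param min_retained minimum visits a subject keeps (default 4).
#' @param seed integer seed; identical seeds give bit-identical cohorts.
#' @return a `simulation_scenario`.
#' @export
simulation_scenario <- function(n_subjects, visit_ages = c(2, 3.5, 5, 7, 9),
                                p_visit_missing = 0, K_true,
                                group_mean_curves, level_sd = 0,
                                noise = list(kind = "independence", sigma = 1),
                                concomitant = NULL,
                                covariate_dist = NULL,
                                min_retained = 4L, seed = 1L) {
  stopifnot(n_subjects >= K_true, K_true >= 1L)
  if (length(group_mean_curves) != K_true) {
    stop_trajmix("group_mean_curves must have exactly K_true entries",
                 "trajmix_config_error")
  }
  if (!is.numeric(noise$sigma) || noise$sigma <= 0) {
    stop_trajmix("noise sigma must be > 0", "trajmix_domain_error")
  }
  if (level_sd < 0 || p_visit_missing < 0 || p_visit_missing > 1) {
    stop_trajmix("invalid level_sd or p_visit_missing",
                 "trajmix_domain_error")
  }
  if (p_visit_missing > 0 && length(visit_ages) < min_retained) {
    stop_trajmix("cannot satisfy the minimum-retained-visits floor",
                 "trajmix_scenario_error")
  }
  if (K_true > 1L) {
    if (is.null(concomitant)) {
      concomitant <- matrix(0, K_true - 1L, 1L,
                            dimnames = list(NULL, "(Intercept)"))
    }
    concomitant <- as.matrix(concomitant)
    stopifnot(nrow(concomitant) == K_true - 1L,
              colnames(concomitant)[1L] == "(Intercept)")
  }
  if (is.null(covariate_dist)) {
    covariate_dist <- function(n) {
      data.frame(sex = rep(c("male", "female"), length.out = n))
    }
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 visit_ages = sort(visit_ages),
                 p_visit_missing = p_visit_missing,
                 K_true = as.integer(K_true),
                 group_mean_curves = group_mean_curves,
                 level_sd = level_sd, noise = noise,
                 concomitant = concomitant,
                 covariate_dist = covariate_dist,
                 min_retained = as.integer(min_retained),
                 seed = as.integer(seed)),
            class = "simulation_scenario")
}

# piecewise-linear shape, centered over the nominal visit design
centered_hinge <- function(slope, knot, visit_ages) {
  raw <- function(t) slope * pmax(t - knot, 0)
  offset <- mean(raw(visit_ages))
  function(t) raw(t) - offset
}

#' Default five-visit childhood-growth scenario
#'
#' A four-group scenario emulating the structure of a five-visit childhood
#' BMI cohort: group 1 linearly increasing, group 2 stable then rising at
#' age 4-5, group 3 stable then rising at age 6-7, group 4 flat; Normal
#' subject-level offsets, independent within-subject noise, and a
#' concomitant model in which a log10 serum-exposure covariate
#' (`log10_ppDDE`) and four confounders (years in the USA, maternal
#' pre-pregnancy BMI, birth weight, breastfeeding duration) shift the group
#' membership probabilities. Marginal group proportions at the covariate
#' means are roughly 14/18/29/39%. See the methods vignette for how each
#' default was chosen.
#'
#' @param seed integer seed.
#' @param n_subjects cohort size (default 500, about 250 per sex).
#' @return a `simulation_scenario` with `K_true = 4`.
#' @export
default_growth_scenario <- function(seed = 1L, n_subjects = 500L) {
  va <- c(2, 3.5, 5, 7, 9)
  curves <- list(
    list(curve = centered_hinge(1.28, 2, va), base = 24.0),   # linear riser
    list(curve = centered_hinge(1.35, 4.5, va), base = 20.8), # rise at 4-5
    list(curve = centered_hinge(1.45, 6.5, va), base = 18.4), # rise at 6-7
    list(curve = function(t) rep(0, length(t)), base = 16.2)  # flat
  )
  # exposure log-odds per unit log10 concentration (ten-fold increase),
  # plus mild confounder effects; intercepts solved so that marginal group
  # proportions at the covariate means are ~ (0.14, 0.18, 0.29, 0.39)
  cov_names <- c("log10_ppDDE", "years_usa", "mat_bmi", "birth_weight_kg",
                 "breastfeed_months")
  cov_means <- c(3.155, 7, 27.7, 3.4, 8)
  slopes <- rbind(
    c(log(1.2), 0.03, 0.08, 0.30, -0.030),
    c(log(3.6), 0.02, 0.05, 0.20, -0.020),
    c(log(2.6), -0.02, 0.02, 0.10, -0.010))
  colnames(slopes) <- cov_names
  target <- c(0.14, 0.18, 0.29, 0.39)
  intercepts <- log(target[1:3] / target[4]) - as.numeric(slopes %*% cov_means)
  gamma_true <- cbind("(Intercept)" = intercepts, slopes)

  covariate_dist <- function(n) {
    sex <- ifelse(stats::runif(n) < 0.546, "female", "male")
    u <- stats::rnorm(n)                     # shared exposure factor
    mix <- function(gm_log10, gsd_log10) {
      gm_log10 + gsd_log10 * (0.7 * u + sqrt(1 - 0.7^2) * stats::rnorm(n))
    }
    log10_opDDT <- mix(log10(1.7), log10(4.3))
    log10_ppDDT <- mix(log10(21.2), log10(5.3))
    log10_ppDDE <- mix(log10(1428), log10(3.4))
    years_usa <- pmin(stats::rlnorm(n, log(5), 0.9), 40)
    mat_bmi <- pmax(stats::rnorm(n, 27.7, 5.6), 16)
    gest_age <- stats::rnorm(n, 39.2, 1.8)
    birth_weight_kg <- pmax(stats::rnorm(n, 3.4, 0.5) - 0.15 * pmax(37 - gest_age, 0), 1.2)
    breastfeed_months <- pmin(stats::rlnorm(n, log(7), 0.9), 36)
    data.frame(sex = sex,
               log10_opDDT = log10_opDDT,
               log10_ppDDT = log10_ppDDT,
               log10_ppDDE = log10_ppDDE,
               years_usa = years_usa,
               mat_bmi = mat_bmi,
               birth_weight_kg = birth_weight_kg,
               breastfeed_months = breastfeed_months,
               gest_age = gest_age,
               preterm = gest_age < 37,
               low_birth_weight = FALSE)  # filled after birth weight draw
  }
  simulation_scenario(
    n_subjects = n_subjects, visit_ages = va, p_visit_missing = 0.04,
    K_true = 4L, group_mean_curves = curves, level_sd = 1.5,
    noise = list(kind = "independence", sigma = 0.6),
    concomitant = gamma_true, covariate_dist = covariate_dist,
    seed = seed)
}

#' Two-group scenario for exposure-effect recovery studies
#'
#' One rising group versus a flat reference group, with a single standard
#' Normal log-scale exposure shifting membership toward the rising group.
#' Used for parameter-recovery and confidence-interval coverage
#' simulations where the true concomitant coefficient must be known.
#'
#' @param seed integer seed.
#' @param n_subjects cohort size (default 800).
#' @param exposure_coef true log-odds per unit exposure for group 1 versus
#'   the reference (default log 3).
#' @param intercept concomitant intercept (default chosen so groups are
#'   roughly balanced at the covariate mean).
#' @return a `simulation_scenario` with `K_true = 2`.
#' @export
two_group_scenario <- function(seed = 1L, n_subjects = 800L,
                               exposure_coef = log(3), intercept = -0.2) {
  va <- c(2, 3.5, 5, 7, 9)
  curves <- list(
    list(curve = centered_hinge(1.2, 3, va), base = 21),
    list(curve = function(t) rep(0, length(t)), base = 17)
  )
  gamma_true <- matrix(c(intercept, exposure_coef), 1L, 2L,
                       dimnames = list(NULL, c("(Intercept)", "exposure")))
  covariate_dist <- function(n) {
    data.frame(sex = rep(c("male", "female"), length.out = n),
               exposure = stats::rnorm(n))
  }
  simulation_scenario(
    n_subjects = n_subjects, visit_ages = va, p_visit_missing = 0.04,
    K_true = 2L, group_mean_curves = curves, level_sd = 1.5,
    noise = list(kind = "independence", sigma = 0.6),
    concomitant = gamma_true, covariate_dist = covariate_dist, seed = seed)
}

#' Simulate a labeled cohort from a scenario
#'
#' Draws, in a fixed order from a single seeded stream: baseline covariates,
#' latent group labels from the concomitant multinomial-logit model,
#' subject-level offsets, visit missingness (with the minimum-retained
#' floor enforced), and within-subject noise at each subject's retained
#' visit ages. Identical seeds give bit-identical cohorts.
#'
#' @param scenario a [simulation_scenario()].
#' @return a `simulated_cohort`: list with `panel` (trajectory_panel),
#'   `baseline` (baseline_table), `true_labels` (named integer vector) and
#'   `scenario`.
#' @export
simulate_cohort <- function(scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  set.seed(scenario$seed)
  n <- scenario$n_subjects
  K <- scenario$K_true
  ids <- sprintf("S%05d", seq_len(n))

  covs <- scenario$covariate_dist(n)
  if (!"sex" %in% names(covs)) {
    stop_trajmix("covariate_dist must return a sex column",
                 "trajmix_scenario_error")
  }
  if ("birth_weight_kg" %in% names(covs)) {
    covs$low_birth_weight <- covs$birth_weight_kg < 2.5
  }

  # latent group: multinomial logit on the concomitant design
  if (K == 1L) {
    groups <- rep(1L, n)
  } else {
    cov_names <- colnames(scenario$concomitant)[-1L]
    missing <- setdiff(cov_names, names(covs))
    if (length(missing)) {
      stop_trajmix(sprintf("covariate_dist lacks concomitant covariate(s): %s",
                           paste(missing, collapse = ", ")),
                   "trajmix_scenario_error")
    }
    Z <- cbind(1, as.matrix(covs[cov_names]))
    eta <- cbind(Z %*% t(scenario$concomitant), 0)
    P <- softmax_rows(eta)
    u <- stats::runif(n)
    cum <- t(apply(P, 1L, cumsum))
    groups <- 1L + rowSums(u > cum)
    groups <- pmin(groups, K)
  }

  offsets <- stats::rnorm(n, 0, scenario$level_sd)

  va <- scenario$visit_ages
  nv <- length(va)
  keep <- matrix(TRUE, n, nv)
  if (scenario$p_visit_missing > 0) {
    drop <- matrix(stats::runif(n * nv) < scenario$p_visit_missing, n, nv)
    for (i in seq_len(n)) {
      while (sum(!drop[i, ]) < scenario$min_retained) {
        restore <- which(drop[i, ])
        drop[i, restore[ceiling(stats::runif(1) * length(restore))]] <- FALSE
      }
    }
    keep <- !drop
  }

  rec_id <- character(0); rec_age <- numeric(0); rec_val <- numeric(0)
  noise <- scenario$noise
  chol_cache <- list()
  for (i in seq_len(n)) {
    ages_i <- va[keep[i, ]]
    m <- length(ages_i)
    g <- groups[i]
    mu <- scenario$group_mean_curves[[g]]$base +
      scenario$group_mean_curves[[g]]$curve(ages_i) + offsets[i]
    z <- stats::rnorm(m)
    eps <- if (identical(noise$kind, "exponential")) {
      key <- paste(ages_i, collapse = "|")
      U <- chol_cache[[key]]
      if (is.null(U)) {
        C <- exp(-abs(outer(ages_i, ages_i, "-")) / noise$phi)
        U <- chol(C)
        chol_cache[[key]] <- U
      }
      noise$sigma * as.numeric(crossprod(U, z))
    } else {
      noise$sigma * z
    }
    rec_id <- c(rec_id, rep(ids[i], m))
    rec_age <- c(rec_age, ages_i)
    rec_val <- c(rec_val, mu + eps)
  }

  panel <- trajectory_panel(rec_id, rec_age, rec_val)
  baseline <- as_baseline_table(cbind(data.frame(subject_id = ids), covs))
  if (!"preterm" %in% names(baseline)) baseline$preterm <- FALSE
  if (!"low_birth_weight" %in% names(baseline)) baseline$low_birth_weight <- FALSE
  true_labels <- stats::setNames(groups, ids)
  structure(list(panel = panel, baseline = baseline,
                 true_labels = true_labels, scenario = scenario),
            class = "simulated_cohort")
}
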