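#' Assemble and validate a pipeline configuration
#'
#' @param cohort either a `simulated_cohort` or a
#'   `list(panel =, baseline =)`; alternatively supply `panel_path` /
#'   `baseline_path` CSVs.
#' @param exposures exposure column names (analysis scale, e.g. log10
#'   concentrations) in the baseline table.
#' @param confounders confounder column names used in adjusted models.
#' @param panel_path,baseline_path CSV paths (used when `cohort` is NULL).
#' @param column_map passed to [read_long_panel()].
#' @param exposure_lods optional named list of LODs; when given, the named
#'   exposure columns are taken as raw concentrations (NA = below LOD) and
#'   log10-transformed with the LOD/2 substitution; columns are renamed
#'   `log10_<name>`.
#' @param min_visits inclusion rule (default 4).
#' @param K_range,cov_kinds model-selection grid.
#' @param em list of EM controls (`tol`, `max_iter`, `n_starts`,
#'   `burn_iter`).
#' @param sensitivity subset rules to refit under (default both
#'   `exclude_preterm` and `exclude_low_birth_weight`; use `character()` to
#'   skip).
#' @param delta covariate increment for the RRR scale.
#' @param ci_method `"full"` or `"two_stage"` (see [wald_ci()]).
#' @param seed integer seed (required).
#' @param out_dir optional output directory; when given, [run_pipeline()]
#'   writes the report tables as CSV plus a `manifest.json`.
#' @return validated `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = NULL, exposures, confounders = character(),
                            panel_path = NULL, baseline_path = NULL,
                            column_map = NULL, exposure_lods = NULL,
                            min_visits = 4L, K_range = 2:5,
                            cov_kinds = c("independence", "exponential"),
                            em = list(), sensitivity = c("exclude_preterm",
                                                         "exclude_low_birth_weight"),
                            delta = 1, ci_method = "full",
                            seed, out_dir = NULL) {
  if (missing(seed) || !is.numeric(seed)) {
    stop_trajmix("a seed is required whenever stochastic steps run",
                 "trajmix_config_error")
  }
  em <- utils::modifyList(list(tol = 1e-8, max_iter = 500L, n_starts = 20L,
                               burn_iter = 15L), em)
  cfg <- list(cohort = cohort, exposures = exposures,
              confounders = confounders, panel_path = panel_path,
              baseline_path = baseline_path, column_map = column_map,
              exposure_lods = exposure_lods, min_visits = min_visits,
              K_range = K_range, cov_kinds = cov_kinds, em = em,
              sensitivity = sensitivity, delta = delta,
              ci_method = ci_method, seed = as.integer(seed),
              out_dir = out_dir,
              nominal_ages = c(2, 3.5, 5, 7, 9))
  class(cfg) <- "pipeline_config"
  cfg
}

load_cohort <- function(config) {
  if (!is.null(config$cohort)) {
    panel <- config$cohort$panel
    baseline <- config$cohort$baseline
  } else {
    cm <- config$column_map %||% c(subject_id = "subject_id",
                                   age = "age_years", value = "value")
    panel <- read_long_panel(config$panel_path, cm)
    baseline <- read_baseline(config$baseline_path)
  }
  if (!is.null(config$exposure_lods)) {
    for (nm in names(config$exposure_lods)) {
      spec <- exposure_spec(nm, config$exposure_lods[[nm]])
      baseline[[paste0("log10_", nm)]] <-
        preprocess_exposure(baseline[[nm]], spec)
    }
  }
  list(panel = panel, baseline = baseline)
}

validate_pipeline <- function(config, panel, baseline) {
  vars <- c(config$exposures, config$confounders)
  unknown <- setdiff(vars, names(baseline))
  if (length(unknown)) {
    stop_trajmix(sprintf("config references unknown covariate(s): %s",
                         paste(unknown, collapse = ", ")),
                 "trajmix_config_error")
  }
  missing <- setdiff(panel_subjects(panel), baseline$subject_id)
  if (length(missing)) {
    stop_trajmix(sprintf("%d panel subject(s) missing from baseline",
                         length(missing)),
                 "trajmix_consistency_error")
  }
  bad_rule <- setdiff(config$sensitivity,
                      c("exclude_preterm", "exclude_low_birth_weight"))
  if (length(bad_rule)) {
    stop_trajmix(sprintf("unknown sensitivity rule(s): %s",
                         paste(bad_rule, collapse = ", ")),
                 "trajmix_config_error")
  }
  invisible(TRUE)
}

#' Run the full trajectory-shape analysis pipeline
#'
#' Sequences the whole analysis: read/accept the cohort, apply the
#' minimum-visit inclusion rule, stratify by sex, mean-center each
#' stratum, select the number of groups and covariance structure by BIC,
#' classify subjects, re-estimate the model with each exposure in the
#' concomitant design (unadjusted and confounder-adjusted), and repeat the
#' adjusted exposure models under the sensitivity subsets. All validation
#' happens before any fitting or file output; identical config and inputs
#' give identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return a `pipeline_bundle`: per-stratum selection results, fits,
#'   classifications, the consolidated RRR table, sensitivity RRR table,
#'   and the report tables from [render_report()]. If `config$out_dir` is
#'   set the report tables are written as CSV with a `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dat <- load_cohort(config)
  validate_pipeline(config, dat$panel, dat$baseline)

  panel <- filter_min_visits(dat$panel, config$min_visits)
  baseline <- dat$baseline
  strata <- stratify(panel, baseline, by = "sex")
  em <- config$em

  fits <- list(); selections <- list(); classifications <- list()
  rrr_rows <- list(); sens_rows <- list()
  for (si in seq_along(strata)) {
    sname <- names(strata)[si]
    st <- strata[[sname]]
    cpanel <- center_trajectories(st$panel)
    sel <- select_model(cpanel, K_range = config$K_range,
                        cov_kinds = config$cov_kinds,
                        n_starts = em$n_starts, max_iter = em$max_iter,
                        tol = em$tol, burn_iter = em$burn_iter,
                        seed = config$seed + 1000L * si)
    selections[[sname]] <- sel
    fits[[sname]] <- sel$fit
    classifications[[sname]] <- classify(sel$fit)
    tab <- adjusted_and_unadjusted(
      st$panel, st$baseline, exposures = config$exposures,
      confounders = config$confounders, K = sel$fit$model$K,
      cov_kind = sel$fit$cov_kind, seed = config$seed + 1000L * si + 17L,
      stratify_sex = FALSE, delta = config$delta,
      base_fits = list(all = sel$fit), ci_method = config$ci_method,
      n_starts = max(3L, em$n_starts %/% 4L),
      max_iter = em$max_iter, tol = em$tol)
    tab$sex <- sname
    rrr_rows[[sname]] <- tab

    for (rule in config$sensitivity) {
      sub <- stratify(st$panel, st$baseline, by = rule)[[1L]]
      if (length(panel_subjects(sub$panel)) ==
          length(panel_subjects(st$panel))) {
        stab <- tab[tab$adjusted, , drop = FALSE]  # nothing excluded
      } else {
        stab <- adjusted_and_unadjusted(
          sub$panel, sub$baseline, exposures = config$exposures,
          confounders = config$confounders, K = sel$fit$model$K,
          cov_kind = sel$fit$cov_kind,
          seed = config$seed + 1000L * si + 29L, stratify_sex = FALSE,
          delta = config$delta, ci_method = config$ci_method,
          n_starts = max(3L, em$n_starts %/% 4L),
          max_iter = em$max_iter, tol = em$tol)
        stab <- stab[stab$adjusted, , drop = FALSE]
        stab$sex <- sname
      }
      stab$subset <- rule
      sens_rows[[paste(sname, rule)]] <- stab
    }
  }

  bundle <- structure(list(
    config = config,
    strata = strata,
    selections = selections,
    fits = fits,
    classifications = classifications,
    rrr_table = do.call(rbind, c(rrr_rows, make.row.names = FALSE)),
    sensitivity_table = if (length(sens_rows)) {
      do.call(rbind, c(sens_rows, make.row.names = FALSE))
    } else NULL
  ), class = "pipeline_bundle")
  bundle$report <- render_report(bundle)

  if (!is.null(config$out_dir)) {
    write_bundle(bundle, config$out_dir)
  }
  bundle
}

#' Render human-readable report tables from a pipeline bundle
#'
#' Produces, per sex stratum: group sizes, raw-outcome summaries (mean,
#' SD) by assigned group and nominal visit age, the posterior-uncertainty
#' summary, the model-selection table, the consolidated RRR table, and the
#' fitted group mean curves on a dense age grid for plotting.
#'
#' @param bundle a `pipeline_bundle` from [run_pipeline()].
#' @return named list of data.frames: `group_sizes`,
#'   `trajectory_summary`, `uncertainty`, `selection`, `rrr_table`,
#'   `curves` (and `sensitivity` when present).
#' @export
render_report <- function(bundle) {
  nominal <- bundle$config$nominal_ages
  gs <- list(); ts <- list(); un <- list(); sel <- list(); cv <- list()
  for (sname in names(bundle$fits)) {
    fit <- bundle$fits[[sname]]
    cl <- bundle$classifications[[sname]]
    labels <- cl$labels
    raw <- bundle$strata[[sname]]$panel
    raw <- raw[raw$subject_id %in% names(labels), , drop = FALSE]
    grp <- labels[raw$subject_id]
    near <- nominal[vapply(raw$age, function(a) which.min(abs(nominal - a)),
                           integer(1))]
    agg_m <- stats::aggregate(raw$value, list(group = grp, age = near), mean)
    agg_s <- stats::aggregate(raw$value, list(group = grp, age = near),
                              stats::sd)
    ts[[sname]] <- data.frame(sex = sname, group = agg_m$group,
                              age = agg_m$age, mean = agg_m$x, sd = agg_s$x)
    tabn <- table(factor(labels, levels = seq_len(fit$model$K)))
    gs[[sname]] <- data.frame(sex = sname,
                              group = as.integer(names(tabn)),
                              n = as.integer(tabn))
    u <- cl$uncertainty; u$sex <- sname
    un[[sname]] <- u[, c("sex", "group", "frac_between_0.1_0.9")]
    s <- bundle$selections[[sname]]$table; s$sex <- sname
    sel[[sname]] <- s[, c("sex", setdiff(names(s), "sex"))]
    cc <- group_curves(fit); cc$sex <- sname
    cv[[sname]] <- cc[, c("sex", "age", "group", "value")]
  }
  rep <- list(group_sizes = do.call(rbind, c(gs, make.row.names = FALSE)),
              trajectory_summary = do.call(rbind, c(ts, make.row.names = FALSE)),
              uncertainty = do.call(rbind, c(un, make.row.names = FALSE)),
              selection = do.call(rbind, c(sel, make.row.names = FALSE)),
              rrr_table = bundle$rrr_table,
              curves = do.call(rbind, c(cv, make.row.names = FALSE)))
  if (!is.null(bundle$sensitivity_table)) {
    rep$sensitivity <- bundle$sensitivity_table
  }
  rep
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(bundle$report)) {
    utils::write.csv(bundle$report[[nm]],
                     file.path(out_dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  for (sname in names(bundle$fits)) {
    post <- bundle$fits[[sname]]$posteriors
    df <- data.frame(subject_id = rownames(post), post,
                     label = bundle$classifications[[sname]]$labels,
                     check.names = FALSE)
    names(df) <- c("subject_id", paste0("prob_", seq_len(ncol(post))),
                   "label")
    utils::write.csv(df, file.path(out_dir,
                                   paste0("posteriors_", sname, ".csv")),
                     row.names = FALSE)
  }
  cfg <- bundle$config
  cfg_public <- cfg[setdiff(names(cfg), c("cohort", "out_dir"))]
  cfg_json <- jsonlite::toJSON(cfg_public, auto_unbox = TRUE, digits = NA,
                               force = TRUE)
  tf <- tempfile(); writeLines(as.character(cfg_json), tf)
  manifest <- list(config = cfg_public,
                   config_md5 = unname(tools::md5sum(tf)),
                   seed = cfg$seed,
                   package_version = as.character(utils::packageVersion("trajmix")),
                   r_version = R.version.string)
  unlink(tf)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}
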