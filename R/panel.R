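#' Construct a longitudinal trajectory panel
#'
#' A trajectory panel is a long-format table of repeated measures: one row
#' per (subject, visit), with the age at the visit in years and the outcome
#' value (typically BMI in kg/m^2). Rows are stored in deterministic
#' subject-then-age order, so identical data always yield identical panels
#' regardless of input row order.
#'
#' @param subject_id vector of subject identifiers (coerced to character).
#' @param age numeric visit ages in years; must be finite and positive.
#' @param value numeric outcome values.
#' @return A `trajectory_panel`: a data.frame with columns `subject_id`,
#'   `age`, `value`, sorted by subject then age.
#' @examples
#' trajectory_panel(c("a", "a", "a"), c(2, 3.5, 5), c(17, 18, 19))
#' @export
trajectory_panel <- function(subject_id, age, value) {
  subject_id <- as.character(subject_id)
  age <- as.numeric(age)
  value <- as.numeric(value)
  n <- length(subject_id)
  if (length(age) != n || length(value) != n) {
    stop_trajmix("subject_id, age and value must have equal length",
                 "trajmix_invalid_panel")
  }
  if (n == 0L) {
    stop_trajmix("no records", "trajmix_invalid_panel")
  }
  if (anyNA(subject_id)) {
    stop_trajmix("missing subject ids", "trajmix_invalid_panel")
  }
  bad_age <- !is.finite(age) | age <= 0
  if (any(bad_age)) {
    stop_trajmix(
      sprintf("ages must be finite and > 0 (first offending row: %d)",
              which(bad_age)[1L]),
      "trajmix_invalid_panel")
  }
  if (anyNA(value) || any(!is.finite(value))) {
    stop_trajmix("outcome values must be finite", "trajmix_invalid_panel")
  }
  df <- data.frame(subject_id = subject_id, age = age, value = value,
                   stringsAsFactors = FALSE)
  df <- df[order(df$subject_id, df$age), , drop = FALSE]
  key <- paste(df$subject_id, format(df$age, digits = 15), sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), , drop = FALSE][1L, ]
    stop_trajmix(
      sprintf("duplicate (subject, age) record: subject '%s' at age %g",
              dup$subject_id, dup$age),
      "trajmix_duplicate_record")
  }
  rownames(df) <- NULL
  class(df) <- c("trajectory_panel", "data.frame")
  df
}

#' @export
print.trajectory_panel <- function(x, ...) {
  cat(sprintf("<trajectory_panel> %d records, %d subjects, ages %g-%g\n",
              nrow(x), length(unique(x$subject_id)),
              min(x$age), max(x$age)))
  NextMethod()
}

#' Subjects present in a panel
#' @param panel a `trajectory_panel`.
#' @return character vector of subject ids in sorted order.
#' @export
panel_subjects <- function(panel) {
  unique(panel$subject_id)
}

#' Read a long-format trajectory panel from CSV
#'
#' Reads a tidy one-row-per-visit CSV and validates it into a
#' [trajectory_panel()]. Column names are remappable so files produced by
#' other systems can be consumed without editing.
#'
#' @param path path to a CSV file.
#' @param column_map named list/vector mapping the canonical names
#'   `subject_id`, `age`, `value` to the column names used in the file.
#'   Defaults to `subject_id`, `age_years`, `value`.
#' @return a `trajectory_panel`.
#' @export
read_long_panel <- function(path,
                            column_map = c(subject_id = "subject_id",
                                           age = "age_years",
                                           value = "value")) {
  if (!file.exists(path)) {
    stop_trajmix(sprintf("file not found: %s", path), "trajmix_config_error")
  }
  column_map <- unlist(column_map)
  needed <- c("subject_id", "age", "value")
  if (!all(needed %in% names(column_map))) {
    stop_trajmix("column_map must name subject_id, age and value",
                 "trajmix_config_error")
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) {
    stop_trajmix("no records", "trajmix_invalid_panel")
  }
  missing_cols <- setdiff(unname(column_map[needed]), names(raw))
  if (length(missing_cols)) {
    stop_trajmix(sprintf("missing column(s): %s",
                         paste(missing_cols, collapse = ", ")),
                 "trajmix_config_error")
  }
  age_raw <- raw[[column_map[["age"]]]]
  val_raw <- raw[[column_map[["value"]]]]
  age <- suppressWarnings(as.numeric(age_raw))
  value <- suppressWarnings(as.numeric(val_raw))
  bad <- which((is.na(age) & !is.na(age_raw)) | (is.na(value) & !is.na(val_raw)))
  if (length(bad)) {
    stop_trajmix(sprintf("non-numeric age/value at row %d", bad[1L]),
                 "trajmix_parse_error")
  }
  trajectory_panel(raw[[column_map[["subject_id"]]]], age, value)
}

#' Read a baseline covariate table from CSV
#'
#' One row per subject: sex, exposure concentrations, confounders and
#' sensitivity flags. Below-LOD exposure values are encoded as empty cells
#' and substituted later by [preprocess_exposure()].
#'
#' @param path path to a CSV with a `subject_id` column and a `sex` column
#'   coded `male`/`female`.
#' @return data.frame of class `baseline_table`, keyed by unique subject_id.
#' @export
read_baseline <- function(path) {
  if (!file.exists(path)) {
    stop_trajmix(sprintf("file not found: %s", path), "trajmix_config_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_baseline_table(df)
}

#' Validate a data.frame as a baseline table
#' @param df data.frame with at least `subject_id` and `sex` columns.
#' @return the validated `baseline_table`.
#' @export
as_baseline_table <- function(df) {
  if (!all(c("subject_id", "sex") %in% names(df))) {
    stop_trajmix("baseline table needs subject_id and sex columns",
                 "trajmix_config_error")
  }
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$subject_id)) {
    stop_trajmix("duplicate subject_id in baseline table",
                 "trajmix_invalid_baseline")
  }
  if (!all(df$sex %in% c("male", "female"))) {
    stop_trajmix("sex must be coded 'male'/'female'",
                 "trajmix_invalid_baseline")
  }
  df <- df[order(df$subject_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("baseline_table", "data.frame")
  df
}

#' Body mass index from weight and height
#'
#' @param weight_kg weight in kilograms, > 0.
#' @param height_m height in meters, > 0.
#' @return BMI in kg/m^2 (weight divided by height squared). Vectorised.
#' @examples
#' compute_bmi(30, 1.25)  # 19.2
#' @export
compute_bmi <- function(weight_kg, height_m) {
  if (any(!is.finite(weight_kg)) || any(!is.finite(height_m)) ||
      any(weight_kg <= 0) || any(height_m <= 0)) {
    stop_trajmix("weight and height must be positive and finite",
                 "trajmix_domain_error")
  }
  weight_kg / height_m^2
}

#' Specification of one exposure analyte
#'
#' @param name exposure name (matching a baseline-table column).
#' @param lod limit of detection, same units as the concentrations
#'   (ng/g lipid); must be > 0.
#' @return an `exposure_spec` list. The transform is fixed as log10.
#' @export
exposure_spec <- function(name, lod) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(lod) || lod <= 0) {
    stop_trajmix("lod must be > 0", "trajmix_domain_error")
  }
  structure(list(name = name, lod = lod, transform = "log10"),
            class = "exposure_spec")
}

#' Preprocess an exposure concentration for analysis
#'
#' Concentrations below the limit of detection are assigned one-half the
#' LOD; all concentrations are then log10-transformed and treated as
#' continuous covariates. `NA` encodes a below-LOD measurement.
#'
#' @param conc numeric concentration(s), ng/g lipid; `NA` marks below-LOD.
#' @param spec an [exposure_spec()].
#' @return log10-scale value(s).
#' @examples
#' preprocess_exposure(100, exposure_spec("ppDDE", lod = 0.5))   # 2
#' preprocess_exposure(NA, exposure_spec("ppDDE", lod = 0.5))    # log10(0.25)
#' @export
preprocess_exposure <- function(conc, spec) {
  stopifnot(inherits(spec, "exposure_spec"))
  out <- numeric(length(conc))
  below <- is.na(conc)
  if (any(!below & conc < 0)) {
    stop_trajmix("negative concentration", "trajmix_domain_error")
  }
  if (any(!below & conc == 0)) {
    stop_trajmix(
      "zero concentration without below-LOD marker: log10 undefined",
      "trajmix_domain_error")
  }
  out[below] <- log10(spec$lod / 2)
  out[!below] <- log10(conc[!below])
  out
}

#' Keep subjects with a minimum number of visits
#'
#' The analysis includes only subjects with near-complete follow-up; the
#' default requires at least 4 of the 5 nominal visits.
#'
#' @param panel a `trajectory_panel`.
#' @param min_visits minimum record count per subject (default 4).
#' @return the filtered `trajectory_panel` (records of retained subjects
#'   unchanged). Idempotent.
#' @export
filter_min_visits <- function(panel, min_visits = 4L) {
  stopifnot(min_visits >= 1L)
  counts <- table(panel$subject_id)
  keep <- names(counts)[counts >= min_visits]
  out <- panel[panel$subject_id %in% keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    stop_trajmix("no subjects satisfy the minimum-visit rule",
                 "trajmix_invalid_panel")
  }
  rownames(out) <- NULL
  class(out) <- c("trajectory_panel", "data.frame")
  out
}

#' Stratify or subset a cohort
#'
#' Either partitions the cohort by sex (for the sex-stratified main
#' analysis) or applies a sensitivity subset rule (dropping preterm or
#' low-birth-weight children).
#'
#' @param panel a `trajectory_panel`.
#' @param baseline a `baseline_table` covering every panel subject.
#' @param by `"sex"` for a partition, or one of `"exclude_preterm"`,
#'   `"exclude_low_birth_weight"` for a sensitivity filter (these require a
#'   logical `preterm` / `low_birth_weight` column in the baseline table).
#' @return a named list of `list(panel =, baseline =)` strata. For `"sex"`
#'   the names are `male`/`female`; for a subset rule there is one stratum
#'   named after the rule.
#' @export
stratify <- function(panel, baseline, by = "sex") {
  stopifnot(inherits(baseline, "baseline_table"))
  subs <- panel_subjects(panel)
  missing <- setdiff(subs, baseline$subject_id)
  if (length(missing)) {
    stop_trajmix(sprintf("panel subject(s) missing from baseline: %s",
                         paste(utils::head(missing, 3L), collapse = ", ")),
                 "trajmix_consistency_error")
  }
  take <- function(ids) {
    p <- panel[panel$subject_id %in% ids, , drop = FALSE]
    rownames(p) <- NULL
    class(p) <- c("trajectory_panel", "data.frame")
    b <- baseline[baseline$subject_id %in% ids, , drop = FALSE]
    rownames(b) <- NULL
    class(b) <- c("baseline_table", "data.frame")
    list(panel = p, baseline = b)
  }
  b_sub <- baseline[match(subs, baseline$subject_id), , drop = FALSE]
  if (identical(by, "sex")) {
    out <- lapply(c(male = "male", female = "female"), function(s) {
      take(b_sub$subject_id[b_sub$sex == s])
    })
    return(out)
  }
  flag <- switch(by,
                 exclude_preterm = "preterm",
                 exclude_low_birth_weight = "low_birth_weight",
                 stop_trajmix(sprintf("unknown stratification rule '%s'", by),
                              "trajmix_config_error"))
  if (!flag %in% names(baseline)) {
    stop_trajmix(sprintf("baseline table lacks '%s' flag", flag),
                 "trajmix_config_error")
  }
  keep <- b_sub$subject_id[!as.logical(b_sub[[flag]])]
  stats::setNames(list(take(keep)), by)
}
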