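#' Remove subject-specific level by mean-centering
#'
#' The clustering targets trajectory *shape*, not level: each subject's
#' observed mean outcome is subtracted from that subject's measurements, so
#' a child who is uniformly heavy and one who is uniformly light but share a
#' growth pattern become indistinguishable to the mixture. Subjects with a
#' single record carry no shape information after centering (their centered
#' vector is identically zero) and are dropped with a warning.
#'
#' @param panel a `trajectory_panel`.
#' @return a `centered_panel`: same layout with `value` replaced by the
#'   centered value, plus attributes `subject_means` (named vector used for
#'   exact inversion) and `dropped_subjects`.
#' @seealso [uncenter_trajectories()]
#' @export
center_trajectories <- function(panel) {
  counts <- table(panel$subject_id)
  singles <- names(counts)[counts < 2L]
  if (length(singles)) {
    warning(sprintf(
      "dropping %d subject(s) with a single record (no shape information): %s",
      length(singles), paste(utils::head(singles, 5L), collapse = ", ")))
    panel <- panel[!panel$subject_id %in% singles, , drop = FALSE]
    if (nrow(panel) == 0L) {
      stop_trajmix("no subjects with >= 2 records", "trajmix_invalid_panel")
    }
  }
  means <- tapply(panel$value, panel$subject_id, mean)
  out <- panel
  out$value <- panel$value - as.numeric(means[panel$subject_id])
  rownames(out) <- NULL
  structure(out,
            subject_means = means[sort(names(means))],
            dropped_subjects = singles,
            class = c("centered_panel", "trajectory_panel", "data.frame"))
}

#' Invert the centering transformation
#'
#' @param cpanel a `centered_panel`.
#' @return the original `trajectory_panel` (dropped single-record subjects
#'   excepted), recovered exactly by adding back the stored means.
#' @export
uncenter_trajectories <- function(cpanel) {
  means <- attr(cpanel, "subject_means")
  out <- as.data.frame(cpanel)
  out$value <- out$value + as.numeric(means[out$subject_id])
  class(out) <- c("trajectory_panel", "data.frame")
  attr(out, "subject_means") <- NULL
  out
}
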