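#' Quadratic B-spline basis for group mean curves
#'
#' Group mean growth patterns are modeled in a B-spline basis: by default
#' quadratic (degree 2) with one internal knot at the median of the pooled
#' observed ages, giving a 4-dimensional curve space. Boundary knots sit at
#' the minimum and maximum observed age. The basis includes the implicit
#' intercept, so the functions form a partition of unity on the age range.
#'
#' @param ages all pooled observed ages (duplicates included — the knot is
#'   the median of the observations, not of the distinct ages).
#' @param degree polynomial degree (default 2, quadratic).
#' @param n_internal number of internal knots (default 1); internal knots
#'   are placed at equally spaced quantiles of `ages`.
#' @return a `spline_basis` with fields `degree`, `internal_knots`,
#'   `boundary_knots` and `dimension` (= degree + 1 + n_internal).
#' @export
build_spline_basis <- function(ages, degree = 2L, n_internal = 1L) {
  ages <- ages[is.finite(ages)]
  distinct <- sort(unique(ages))
  if (length(distinct) < 3L) {
    stop_trajmix("need >= 3 distinct ages to build a spline basis",
                 "trajmix_basis_error")
  }
  stopifnot(degree >= 1L, n_internal >= 0L)
  boundary <- range(distinct)
  internal <- if (n_internal > 0L) {
    as.numeric(stats::quantile(ages, probs = seq_len(n_internal) / (n_internal + 1),
                               type = 7, names = FALSE))
  } else numeric(0)
  structure(list(degree = as.integer(degree),
                 internal_knots = internal,
                 boundary_knots = boundary,
                 dimension = as.integer(degree + 1L + n_internal)),
            class = "spline_basis")
}

#' Evaluate a spline basis at given ages
#'
#' @param basis a `spline_basis`.
#' @param ages ages within the basis boundary (clamped to the boundary, so
#'   fitted curves can be evaluated at the extreme visits).
#' @return matrix with `length(ages)` rows and `basis$dimension` columns;
#'   rows sum to 1 (partition of unity).
#' @export
eval_basis <- function(basis, ages) {
  stopifnot(inherits(basis, "spline_basis"))
  lo <- basis$boundary_knots[1L]
  hi <- basis$boundary_knots[2L]
  x <- pmin(pmax(ages, lo), hi)
  ord <- basis$degree + 1L
  knots <- c(rep(lo, ord), basis$internal_knots, rep(hi, ord))
  splines::splineDesign(knots = knots, x = x, ord = ord)
}
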