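#' Within-subject working covariance models
#'
#' Two working covariance structures for a subject's centered repeated
#' measures, both with constant variance across visits:
#' * `independence`: sigma2 times the identity;
#' * `exponential`: entries sigma2 * exp(-|t_s - t_u| / phi), correlation
#'   decaying with the age gap at range phi (years).
#'
#' Exact within-subject centering makes the true covariance of a centered
#' vector rank-deficient; these are deliberately *working* models fit to the
#' transformed data (see the methods vignette).
#'
#' @param kind `"independence"` or `"exponential"`.
#' @param sigma2 variance, > 0.
#' @param phi correlation range in years, > 0 (exponential only).
#' @return a `covariance_model`.
#' @export
covariance_model <- function(kind = c("independence", "exponential"),
                             sigma2, phi = NULL) {
  kind <- match.arg(kind)
  if (!is.finite(sigma2) || sigma2 <= 0) {
    stop_trajmix("sigma2 must be > 0", "trajmix_domain_error")
  }
  if (kind == "exponential") {
    if (is.null(phi) || !is.finite(phi) || phi <= 0) {
      stop_trajmix("phi must be > 0 for the exponential structure",
                   "trajmix_domain_error")
    }
  } else {
    phi <- NULL
  }
  structure(list(kind = kind, sigma2 = sigma2, phi = phi),
            class = "covariance_model")
}

#' Covariance matrix at a subject's visit ages
#'
#' @param cov a `covariance_model`.
#' @param ages distinct, finite visit ages.
#' @return symmetric positive-definite matrix of order `length(ages)`.
#' @export
covariance_matrix <- function(cov, ages) {
  stopifnot(inherits(cov, "covariance_model"))
  if (anyDuplicated(ages) || any(!is.finite(ages))) {
    stop_trajmix("ages must be distinct and finite", "trajmix_domain_error")
  }
  m <- length(ages)
  if (cov$kind == "independence") {
    return(diag(cov$sigma2, m))
  }
  d <- abs(outer(ages, ages, "-"))
  cov$sigma2 * exp(-d / cov$phi)
}
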