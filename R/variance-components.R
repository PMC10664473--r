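#' Variance components of the random slopes model
#'
#' The random slopes model gives each person a Gaussian random intercept
#' \eqn{u_0} and random slope \eqn{u_1} with covariance matrix
#' \eqn{[[\sigma^2_{u0}, \sigma_{u01}], [\sigma_{u01}, \sigma^2_{u1}]]},
#' plus i.i.d. residual error with variance \eqn{\sigma^2_e}. These four
#' parameters determine both the simulator's covariance structure and the
#' marginal covariance used in the sample-size formula.
#'
#' The defaults are the reference parameter set used throughout the
#' package's simulation scenarios: intercept variance 0.5, slope variance
#' 0.01, intercept-slope correlation 0.5 (so covariance
#' \eqn{0.5\sqrt{0.005}}), residual variance 0.15.
#'
#' @param sigma2_u0 Random-intercept variance (outcome^2), >= 0.
#' @param sigma2_u1 Random-slope variance (outcome^2/year^2), >= 0.
#' @param sigma_u01 Intercept-slope covariance (outcome^2/year); must satisfy
#'   `sigma_u01^2 <= sigma2_u0 * sigma2_u1`.
#' @param sigma2_e Residual error variance (outcome^2), > 0.
#' @return An object of class `variance_components` (a named list).
#' @examples
#' variance_components()
#' variance_components(sigma2_e = 2)
#' @export
variance_components <- function(sigma2_u0 = 0.5,
                                sigma2_u1 = 0.01,
                                sigma_u01 = 0.5 * sqrt(0.005),
                                sigma2_e = 0.15) {
  vals <- c(sigma2_u0 = sigma2_u0, sigma2_u1 = sigma2_u1,
            sigma_u01 = sigma_u01, sigma2_e = sigma2_e)
  if (!is.numeric(vals) || length(vals) != 4 || any(!is.finite(vals))) {
    abort("All four variance components must be finite numbers.")
  }
  if (sigma2_u0 < 0 || sigma2_u1 < 0) {
    abort("`sigma2_u0` and `sigma2_u1` must be non-negative.")
  }
  if (sigma2_e <= 0) {
    abort("`sigma2_e` must be strictly positive.")
  }
  if (sigma_u01^2 > sigma2_u0 * sigma2_u1 * (1 + 1e-12)) {
    abort("`sigma_u01`^2 must not exceed `sigma2_u0 * sigma2_u1`.")
  }
  structure(as.list(vals), class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat("<variance components>\n")
  cat(sprintf("  sigma2_u0: %.6g  (random-intercept variance)\n", x$sigma2_u0))
  cat(sprintf("  sigma2_u1: %.6g  (random-slope variance)\n", x$sigma2_u1))
  cat(sprintf("  sigma_u01: %.6g  (intercept-slope covariance)\n", x$sigma_u01))
  cat(sprintf("  sigma2_e:  %.6g  (residual variance)\n", x$sigma2_e))
  rho <- vc_correlation(x)
  if (is.finite(rho)) cat(sprintf("  implied correlation: %.4f\n", rho))
  invisible(x)
}

as_variance_components <- function(x) {
  if (inherits(x, "variance_components")) return(x)
  x <- unlist(x)
  if (length(x) != 4) abort("Expected four variance components.")
  if (is.null(names(x)) || !all(c("sigma2_u0", "sigma2_u1", "sigma_u01",
                                  "sigma2_e") %in% names(x))) {
    names(x) <- c("sigma2_u0", "sigma2_u1", "sigma_u01", "sigma2_e")
  }
  variance_components(x[["sigma2_u0"]], x[["sigma2_u1"]],
                      x[["sigma_u01"]], x[["sigma2_e"]])
}

vc_correlation <- function(vc) {
  denom <- sqrt(vc$sigma2_u0 * vc$sigma2_u1)
  if (denom == 0) return(NA_real_)
  vc$sigma_u01 / denom
}

#' Validate a visit schedule
#'
#' A visit schedule is a strictly increasing numeric vector of visit times
#' in years whose first element is 0 (baseline). Schedules are shared by the
#' data generator, the fitted models' design matrices, and the sample-size
#' calculator.
#'
#' @param times Numeric vector of visit times in years.
#' @return The validated schedule (numeric vector).
#' @examples
#' visit_schedule(0:5)
#' @export
visit_schedule <- function(times) {
  times <- as.numeric(times)
  if (length(times) < 2) abort("A schedule needs at least 2 visits.")
  if (times[1] != 0) abort("The first visit time must be 0 (baseline).")
  if (any(diff(times) <= 0)) abort("Visit times must be strictly increasing.")
  times
}
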