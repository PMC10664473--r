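# Two-stage sample-size machinery for random-slopes trials.
#
# The treatment-effect variance is computed for a hypothetical 2-person
# trial (one control, one treated subject over the schedule) and scaled by
# N/2; the total sample size is then the usual normal-quantile formula on
# the slope-difference scale.

# internal: marginal covariance from a named numeric vector of components
sigma_person_ <- function(v, times) {
  outer(times, times, function(a, b) {
    v[["sigma2_u0"]] + a * b * v[["sigma2_u1"]] + (a + b) * v[["sigma_u01"]]
  }) + diag(v[["sigma2_e"]], length(times))
}

#' Marginal per-person covariance implied by the random slopes model
#'
#' Entry \eqn{(j,k)} is \eqn{\sigma^2_{u0} + t_j t_k \sigma^2_{u1} +
#' (t_j + t_k)\sigma_{u01} + 1\{j=k\}\sigma^2_e}. Because the random
#' slopes model is parametric in time, this covariance can be evaluated on
#' any visit schedule, including schedules not present in the data the
#' components were estimated from.
#'
#' @param vc A [variance_components()] object.
#' @param times Visit times in years (validated by [visit_schedule()]).
#' @return An `n_visits` x `n_visits` positive-definite matrix.
#' @examples
#' sigma_person(variance_components(), 0:5)[1, 1]  # 0.65
#' @export
sigma_person <- function(vc, times) {
  vc <- as_variance_components(vc)
  times <- visit_schedule(times)
  sigma_person_(unlist(vc), times)
}

#' Design and covariance of the hypothetical 2-person trial
#'
#' Builds the stacked fixed-effects design (columns \eqn{\beta_0},
#' \eqn{\beta_1}, \eqn{\gamma}) and block-diagonal marginal covariance for
#' one control and one treated person over the schedule, the device used
#' to compute the treatment-effect variance for any trial size.
#'
#' @inheritParams sigma_person
#' @param schedule Visit times in years, baseline 0.
#' @return A list with elements `X` (2 n_visits x 3), `Sigma`
#'   (2 n_visits square), `schedule`.
#' @export
two_person_design <- function(vc, schedule) {
  vc <- as_variance_components(vc)
  times <- visit_schedule(schedule)
  nv <- length(times)
  X <- rbind(arm_design("rs_trial", times, 0), arm_design("rs_trial", times, 1))
  colnames(X) <- c("beta0", "beta1", "gamma")
  S <- sigma_person_(unlist(vc), times)
  Sigma <- matrix(0, 2 * nv, 2 * nv)
  Sigma[1:nv, 1:nv] <- S
  Sigma[(nv + 1):(2 * nv), (nv + 1):(2 * nv)] <- S
  list(X = X, Sigma = Sigma, schedule = times)
}

#' Variance of the treatment-slope estimate in a 2-person trial
#'
#' The \eqn{(3,3)} element of \eqn{(X^T\Sigma^{-1}X)^{-1}} for the
#' [two_person_design()]; dividing by \eqn{N/2} gives the variance for an
#' N-person trial with 1:1 allocation.
#'
#' @inheritParams two_person_design
#' @return The variance of \eqn{\hat\gamma} (outcome^2/year^2).
#' @examples
#' var_gamma_two_person(variance_components(), 0:5)
#' @export
var_gamma_two_person <- function(vc, schedule) {
  d <- two_person_design(vc, schedule)
  ch <- tryCatch(chol(d$Sigma), error = function(e) {
    abort("Singular two-person covariance for this design.")
  })
  Xw <- backsolve(ch, d$X, transpose = TRUE)
  A <- crossprod(Xw)
  V <- tryCatch(solve(A), error = function(e) {
    abort("Singular information matrix: the design cannot identify the slope difference.")
  })
  V[3, 3]
}

#' Scale the 2-person variance to an N-person trial
#'
#' @param v2 Variance of the slope difference from a 2-person trial.
#' @param n_total Total trial size; must be even and >= 2.
#' @return `v2 / (n_total / 2)`.
#' @export
scale_variance <- function(v2, n_total) {
  if (n_total %% 2 != 0 || n_total < 2) {
    abort("`n_total` must be even and at least 2.")
  }
  v2 / (n_total / 2)
}

#' Total sample size for a random-slopes trial
#'
#' \deqn{N = 2\left\lceil \frac{(z_{1-\alpha/2} + z_{power})^2}{d^2}
#'   V(\hat\gamma) \right\rceil}
#' where \eqn{V(\hat\gamma)} is the 2-person-trial variance of the
#' treatment slope, \eqn{d} the target difference in slopes (outcome/year),
#' \eqn{\alpha} the two-sided type-I error and `power` = \eqn{1-\beta}.
#' The ceiling makes the returned total always even.
#'
#' @inheritParams two_person_design
#' @param d Target treatment effect as a difference in slopes
#'   (outcome/year); non-zero.
#' @param alpha Two-sided type-I error, in (0, 1).
#' @param power Target power, in (0, 1).
#' @return Even integer total sample size.
#' @examples
#' slopes_sample_size(variance_components(), d = -0.05, schedule = 0:5)
#' @export
slopes_sample_size <- function(vc, d, schedule = 0:5, alpha = 0.05,
                               power = 0.8) {
  stopifnot(is.numeric(d), length(d) == 1, d != 0,
            alpha > 0, alpha < 1, power > 0, power < 1)
  v2 <- var_gamma_two_person(vc, schedule)
  bracket <- (qnorm(1 - alpha / 2) + qnorm(power))^2 * v2 / d^2
  2L * as.integer(ceiling(bracket - 1e-12))
}

#' Analytic power of the slope test at a given trial size
#'
#' Normal-approximation power \eqn{\Phi(|d|/\sqrt{V_N} - z_{1-\alpha/2})}
#' with \eqn{V_N} the scaled 2-person variance. Useful for checking that
#' the returned sample size attains the requested power.
#'
#' @inheritParams slopes_sample_size
#' @param n_total Total trial size (even).
#' @return Power as a proportion in (0, 1).
#' @export
analytic_power <- function(vc, d, schedule, n_total, alpha = 0.05) {
  vN <- scale_variance(var_gamma_two_person(vc, schedule), n_total)
  pnorm(abs(d) / sqrt(vN) - qnorm(1 - alpha / 2))
}

#' Large-sample expectation of the treatment slope under any mean profile
#'
#' When the random slopes model is fitted to data whose true group mean
#' difference is not proportional to time, the estimated slope difference
#' converges to a covariance-weighted linear combination of the per-visit
#' group mean differences. This function computes that pseudo-true value:
#' element \eqn{\gamma} of \eqn{(X^T\Sigma^{-1}X)^{-1}X^T\Sigma^{-1}\mu}
#' for the 2-person design, with \eqn{\mu} the stacked (control, treated)
#' mean vectors and \eqn{\Sigma} built from `vc_pseudo`.
#'
#' `vc_pseudo` should be the covariance the fitted model would converge to;
#' a practical default is the random-slopes fit to a large simulated
#' control-arm cohort under the target generating mechanism.
#'
#' @param mu_control,mu_treated Mean outcome vectors over the schedule.
#' @param vc_pseudo [variance_components()] used to weight the visits.
#' @inheritParams two_person_design
#' @return The pseudo-true slope difference (outcome/year).
#' @examples
#' sched <- 0:5
#' mu_c <- control_mean("early", sched)
#' mu_t <- treated_mean("early",
#'   treatment_effect("proportional_control_change", -0.05), sched)
#' expected_rs_effect(mu_c, mu_t, variance_components(), sched)
#' @export
expected_rs_effect <- function(mu_control, mu_treated, vc_pseudo,
                               schedule) {
  d <- two_person_design(vc_pseudo, schedule)
  nv <- length(d$schedule)
  if (length(mu_control) != nv || length(mu_treated) != nv) {
    abort("Mean vectors must have one value per scheduled visit.")
  }
  mu <- c(mu_control, mu_treated)
  ch <- chol(d$Sigma)
  Xw <- backsolve(ch, d$X, transpose = TRUE)
  muw <- backsolve(ch, mu, transpose = TRUE)
  beta <- solve(crossprod(Xw), crossprod(Xw, muw))
  drop(beta[3])
}

#' Sample size as a function of trial length
#'
#' Applies [slopes_sample_size()] over schedules of increasing length with
#' a fixed visit interval, to show how the required size falls as a trial
#' is lengthened (and how the answer depends on the covariance parameters
#' fed in).
#'
#' @inheritParams slopes_sample_size
#' @param lengths Positive trial lengths in years.
#' @param visit_interval Spacing of visits in years (default 1, annual).
#' @return A tibble of class `slopes_ss_curve` with columns `length`,
#'   `n_visits`, `n_total`.
#' @examples
#' sample_size_curve(variance_components(), d = -0.05, lengths = 2:7)
#' @export
sample_size_curve <- function(vc, d, alpha = 0.05, power = 0.8,
                              lengths = 2:7, visit_interval = 1) {
  stopifnot(all(lengths > 0), visit_interval > 0)
  rows <- purrr::map(lengths, function(L) {
    sched <- seq(0, L, by = visit_interval)
    if (tail(sched, 1) < L) sched <- c(sched, L)
    tibble::tibble(
      length = L,
      n_visits = length(sched),
      n_total = slopes_sample_size(vc, d, sched, alpha, power)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("slopes_ss_curve", class(out))
  out
}

#' Two-stage sample size from pilot/observational data
#'
#' The workflow used when planning a real trial: fit the observational
#' random slopes model (no treatment term) to an existing long-format
#' dataset, then size the trial from the estimated variance components.
#'
#' @param data Long pilot/observational data (`subject_id`, `arm`, `time`,
#'   `y`), typically all `arm = 0`.
#' @inheritParams slopes_sample_size
#' @return A list with the fitted `slopes_rs_fit` (`fit`), the 2-person
#'   variance `v_gamma`, and the total size `n_total`.
#' @examples
#' pilot <- simulate_observational("steady", n_subjects = 200, seed = 9)
#' sample_size_from_pilot(pilot, d = -0.05, schedule = 0:3)$n_total
#' @export
sample_size_from_pilot <- function(data, d, schedule = 0:5, alpha = 0.05,
                                   power = 0.8) {
  fit <- fit_with_ladder(data, "observational")
  if (!fit$converged) {
    abort("The observational random slopes fit did not converge.")
  }
  v2 <- var_gamma_two_person(fit$vc_hat, schedule)
  list(
    fit = fit,
    v_gamma = v2,
    n_total = slopes_sample_size(fit$vc_hat, d, schedule, alpha, power)
  )
}
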