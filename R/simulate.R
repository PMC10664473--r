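#' Draw per-subject random intercepts and slopes
#'
#' Samples `n` i.i.d. pairs \eqn{(u_0, u_1)} from a zero-mean bivariate
#' Gaussian with covariance determined by the [variance_components()].
#' Degenerate components (zero variances) are handled exactly rather than
#' through a failed Cholesky factor.
#'
#' @param vc A [variance_components()] object.
#' @param n Number of subjects.
#' @param seed Optional integer seed; when supplied the caller's RNG state
#'   is left untouched.
#' @return A tibble with columns `u0` and `u1`, one row per subject.
#' @examples
#' draw_subject_effects(variance_components(), 5, seed = 1)
#' @export
draw_subject_effects <- function(vc, n, seed = NULL) {
  vc <- as_variance_components(vc)
  stopifnot(is.numeric(n), length(n) == 1, n >= 1)
  n <- as.integer(n)
  with_seed_or_current(seed, {
    z1 <- rnorm(n)
    z2 <- rnorm(n)
    s0 <- vc$sigma2_u0
    s1 <- vc$sigma2_u1
    s01 <- vc$sigma_u01
    if (s0 > 0) {
      u0 <- sqrt(s0) * z1
      cond <- s1 - s01^2 / s0
      u1 <- (s01 / sqrt(s0)) * z1 + sqrt(max(cond, 0)) * z2
    } else {
      u0 <- rep(0, n)
      u1 <- sqrt(s1) * z2
    }
    tibble::tibble(u0 = u0, u1 = u1)
  })
}

simulate_arm <- function(shape, mean_fun, vc, times, n, id_offset, arm) {
  nv <- length(times)
  eff <- draw_subject_effects(vc, n)
  mu <- mean_fun(times)
  # residuals drawn subject-major so each subject's record block is
  # contiguous and reproducible independent of nv ordering conventions
  e <- rnorm(n * nv, sd = sqrt(vc$sigma2_e))
  tibble::tibble(
    subject_id = rep(id_offset + seq_len(n), each = nv),
    arm = arm,
    time = rep(times, n),
    y = rep(mu, n) + rep(eff$u0, each = nv) +
      rep(eff$u1, each = nv) * rep(times, n) + e
  )
}

#' Simulate an observational (untreated) cohort
#'
#' Generates a balanced, complete long-format dataset
#' \deqn{y_{ij} = 6 + 0.2 f(t_j) + u_{0i} + u_{1i} t_j + e_{ij}}
#' for `n_subjects` untreated people over the visit schedule. Non-linearity
#' enters only through the fixed mean \eqn{f(t)}; the random-effect
#' contribution \eqn{u_{1i} t_j} is linear in time for every shape, so all
#' shapes share the same covariance structure.
#'
#' @inheritParams f_shape
#' @inheritParams draw_subject_effects
#' @param schedule Visit times in years (validated by [visit_schedule()]).
#' @param n_subjects Number of subjects (>= 2).
#' @param baseline,scale Mean-trajectory constants, see [control_mean()].
#' @return A tibble with columns `subject_id`, `arm` (all 0), `time`, `y`;
#'   one row per subject-visit.
#' @examples
#' obs <- simulate_observational("early", n_subjects = 50, seed = 7)
#' head(obs)
#' @export
simulate_observational <- function(shape,
                                   vc = variance_components(),
                                   schedule = 0:5,
                                   n_subjects = 1000,
                                   seed = NULL,
                                   baseline = 6, scale = 0.2) {
  shape <- match_shape(shape)
  vc <- as_variance_components(vc)
  times <- visit_schedule(schedule)
  if (n_subjects < 2) abort("`n_subjects` must be at least 2.")
  with_seed_or_current(seed, {
    simulate_arm(shape, function(t) control_mean(shape, t, baseline, scale),
                 vc, times, as.integer(n_subjects), 0L, 0L)
  })
}

#' Simulate a 1:1 randomised trial
#'
#' Generates a two-arm trial of `n_total` subjects with exact 1:1
#' allocation. The control arm follows the same generator as
#' [simulate_observational()]; the treated arm's mean follows
#' [treated_mean()] under the given [treatment_effect()]. Random-effect and
#' residual distributions are identical in both arms. Subject ids are
#' shuffled after allocation so id order carries no arm information.
#'
#' @inheritParams simulate_observational
#' @param effect A [treatment_effect()] specification.
#' @param n_total Total number of subjects; must be even.
#' @return A tibble with columns `subject_id`, `arm` (0 control, 1 treated),
#'   `time`, `y`.
#' @examples
#' trial <- simulate_trial("steady", treatment_effect("proportional_time", -0.05),
#'                         n_total = 40, seed = 3)
#' dplyr::count(trial, arm)
#' @export
simulate_trial <- function(shape,
                           effect,
                           vc = variance_components(),
                           schedule = 0:5,
                           n_total = 100,
                           seed = NULL,
                           baseline = 6, scale = 0.2) {
  shape <- match_shape(shape)
  stopifnot(inherits(effect, "slopes_effect"))
  vc <- as_variance_components(vc)
  times <- visit_schedule(schedule)
  if (n_total %% 2 != 0 || n_total < 2) {
    abort("`n_total` must be an even number of subjects (1:1 allocation).")
  }
  n_arm <- as.integer(n_total / 2)
  with_seed_or_current(seed, {
    ctrl <- simulate_arm(
      shape, function(t) control_mean(shape, t, baseline, scale),
      vc, times, n_arm, 0L, 0L
    )
    trt <- simulate_arm(
      shape, function(t) treated_mean(shape, effect, t, baseline, scale),
      vc, times, n_arm, n_arm, 1L
    )
    out <- dplyr::bind_rows(ctrl, trt)
    # relabel subject ids with a random permutation (exact 1:1 allocation,
    # ids uninformative about arm), then return in id order
    perm <- sample.int(n_total)
    out$subject_id <- perm[out$subject_id]
    dplyr::arrange(out, .data$subject_id, .data$time)
  })
}
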