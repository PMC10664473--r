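#' Trajectory shapes for the mean outcome in untreated people
#'
#' Four time-transform functions \eqn{f(t)} describe how the mean outcome
#' deteriorates over follow-up in people not receiving the trial treatment.
#' All four are calibrated so that \eqn{f(0) \approx 0} and
#' \eqn{f(5) \approx 5}: the mean trajectories they generate share their
#' start and (to 2 decimal places) their end point over a 5-year window, and
#' differ only in when the decline happens.
#'
#' * `steady`: \eqn{f(t) = t}, a linear trajectory.
#' * `early`: \eqn{f(t) = -5 e^{-2t} + 5}, most change early in follow-up.
#' * `late`: \eqn{f(t) = e^{2t} / 4400}, most change late in follow-up.
#' * `intermediate`: \eqn{f(t) = -5 / (1 + e^{-3(2.5 - t)}) + 5}, a logistic
#'   decline centred at 2.5 years.
#'
#' @param shape Character scalar: one of `"steady"`, `"early"`, `"late"`,
#'   `"intermediate"`.
#' @param t Numeric vector of non-negative times in years.
#' @return `f_shape()` returns the unitless transformed time, same length
#'   as `t`.
#' @examples
#' f_shape("steady", 3)
#' f_shape("late", 5)
#' @export
f_shape <- function(shape, t) {
  shape <- match_shape(shape)
  stopifnot(is.numeric(t), all(t >= 0))
  switch(shape,
    steady = t,
    early = -5 * exp(-2 * t) + 5,
    late = exp(2 * t) / 4400,
    intermediate = -5 / (1 + exp(-3 * (2.5 - t))) + 5
  )
}

#' @rdname f_shape
#' @export
trajectory_shapes <- function() {
  c("steady", "early", "late", "intermediate")
}

match_shape <- function(shape) {
  if (!is.character(shape) || length(shape) != 1 ||
      !shape %in% trajectory_shapes()) {
    abort(paste0(
      "`shape` must be one of ",
      paste0('"', trajectory_shapes(), '"', collapse = ", "), "."
    ))
  }
  shape
}

#' Mean outcome trajectories in the control and treated groups
#'
#' The mean outcome for untreated people is \eqn{6 + 0.2 f(t)}: every shape
#' starts at 6 and ends at 7.00 (2 dp) at five years, with higher values
#' indicating a worse outcome. `treated_mean()` adds a treatment effect on
#' top of the control trajectory according to a [treatment_effect()]
#' specification.
#'
#' @inheritParams f_shape
#' @param baseline Mean outcome at time zero (default 6).
#' @param scale Multiplier applied to the transformed time (default 0.2).
#' @return Numeric vector of mean outcomes, same length as `t`.
#' @seealso [f_shape()], [treatment_effect()]
#' @examples
#' control_mean("early", 0:5)
#' treated_mean("steady", treatment_effect("proportional_time", -0.05), 5)
#' @export
control_mean <- function(shape, t, baseline = 6, scale = 0.2) {
  baseline + scale * f_shape(shape, t)
}

#' Treatment-effect specifications
#'
#' Describes how the treated-group mean trajectory differs from the control
#' trajectory:
#'
#' * `none`: no effect; the treated mean equals the control mean.
#' * `proportional_time`: the group difference grows linearly,
#'   \eqn{\gamma t} — the shape the random slopes model assumes.
#' * `proportional_control_change`: the difference is proportional to the
#'   control group's own change from baseline, \eqn{\gamma f(t)}.
#' * `delayed_decline`: the treated mean is flat for `delay` years and then
#'   mirrors the control trajectory shifted right by `delay`; only defined
#'   for the `steady` shape (for which the two proportional effects would
#'   coincide).
#'
#' @param kind One of `"none"`, `"proportional_time"`,
#'   `"proportional_control_change"`, `"delayed_decline"`.
#' @param gamma Effect rate: outcome/year for `proportional_time`, a
#'   multiplier of \eqn{f(t)} for `proportional_control_change`. Ignored
#'   for `none` and `delayed_decline`.
#' @param delay Delay in years before the treated group starts to decline
#'   (`delayed_decline` only).
#' @return An object of class `slopes_effect`.
#' @examples
#' treatment_effect("proportional_control_change", gamma = -0.05)
#' treatment_effect("delayed_decline", delay = 1.25)
#' @export
treatment_effect <- function(kind = c("none", "proportional_time",
                                      "proportional_control_change",
                                      "delayed_decline"),
                             gamma = NULL, delay = NULL) {
  kind <- match.arg(kind)
  if (kind %in% c("proportional_time", "proportional_control_change")) {
    if (is.null(gamma) || !is.numeric(gamma) || length(gamma) != 1) {
      abort("`gamma` must be a numeric scalar for proportional effects.")
    }
  }
  if (kind == "delayed_decline") {
    if (is.null(delay) || !is.numeric(delay) || length(delay) != 1 ||
        delay < 0) {
      abort("`delay` must be a non-negative scalar for delayed decline.")
    }
  }
  structure(
    list(kind = kind, gamma = gamma, delay = delay),
    class = "slopes_effect"
  )
}

#' @export
print.slopes_effect <- function(x, ...) {
  cat("<treatment effect:", x$kind, ">\n")
  if (!is.null(x$gamma)) cat("  gamma:", x$gamma, "\n")
  if (!is.null(x$delay)) cat("  delay:", x$delay, "years\n")
  invisible(x)
}

#' @rdname control_mean
#' @param effect A [treatment_effect()] specification.
#' @export
treated_mean <- function(shape, effect, t, baseline = 6, scale = 0.2) {
  shape <- match_shape(shape)
  stopifnot(inherits(effect, "slopes_effect"))
  ctrl <- control_mean(shape, t, baseline, scale)
  switch(effect$kind,
    none = ctrl,
    proportional_time = ctrl + effect$gamma * t,
    proportional_control_change = ctrl + effect$gamma * f_shape(shape, t),
    delayed_decline = {
      if (shape != "steady") {
        abort("Delayed decline is only defined for the steady shape.")
      }
      ifelse(t <= effect$delay,
             baseline,
             baseline + scale * f_shape(shape, pmax(t - effect$delay, 0)))
    }
  )
}
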