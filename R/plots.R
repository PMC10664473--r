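# ggplot2 views of the generator, the sample-size curves and the
# Monte-Carlo performance summaries.

#' Plot mean outcome trajectories
#'
#' Shows the control-group mean trajectory for each requested shape and,
#' when an effect is supplied, the treated-group trajectory alongside it.
#'
#' @param shapes Trajectory shapes to draw.
#' @param effect Optional [treatment_effect()]; drawn only for shapes it is
#'   valid for.
#' @param t_max Follow-up length in years.
#' @return A ggplot object.
#' @examples
#' plot_mean_trajectories()
#' @export
plot_mean_trajectories <- function(shapes = trajectory_shapes(),
                                   effect = NULL, t_max = 5) {
  tt <- seq(0, t_max, length.out = 201)
  dat <- purrr::map(shapes, function(s) {
    rows <- tibble::tibble(shape = s, time = tt, group = "control",
                           mean = control_mean(s, tt))
    if (!is.null(effect) &&
        (effect$kind != "delayed_decline" || s == "steady")) {
      rows <- dplyr::bind_rows(rows, tibble::tibble(
        shape = s, time = tt, group = "treated",
        mean = treated_mean(s, effect, tt)
      ))
    }
    rows
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time, y = .data$mean,
                                    linetype = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$shape)) +
    ggplot2::labs(x = "Time (years)", y = "Mean outcome",
                  linetype = NULL) +
    ggplot2::theme_bw()
}

#' Spaghetti plot of simulated subjects
#'
#' @param data Long data from [simulate_observational()] or
#'   [simulate_trial()].
#' @param n_subjects Number of subjects to draw (sampled in id order).
#' @return A ggplot object.
#' @export
plot_spaghetti <- function(data, n_subjects = 20) {
  ids <- head(sort(unique(data$subject_id)), n_subjects)
  d <- dplyr::filter(data, .data$subject_id %in% ids)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$y,
                                  group = .data$subject_id,
                                  colour = factor(.data$arm))) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::labs(x = "Time (years)", y = "Outcome", colour = "Arm") +
    ggplot2::theme_bw()
}

#' @describeIn sample_size_curve Plot the size-versus-length curve.
#' @param object A `slopes_ss_curve` tibble.
#' @param ... Unused.
#' @export
autoplot.slopes_ss_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$length,
                                       y = .data$n_total)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Trial length (years)", y = "Total sample size") +
    ggplot2::theme_bw()
}

#' @describeIn run_scenario Plot per-model rejection rates with 95%
#'   Monte-Carlo error bars.
#' @param object A `slopes_perf` tibble.
#' @param ... Unused.
#' @export
autoplot.slopes_perf <- function(object, ...) {
  cfg <- attr(object, "config")
  nominal <- if (cfg$effect_kind == "none") 100 * cfg$alpha else
    100 * cfg$power_target
  ggplot2::ggplot(object, ggplot2::aes(x = .data$model,
                                       y = .data$reject_pct)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$reject_pct - 1.96 * .data$reject_mc_se,
      ymax = .data$reject_pct + 1.96 * .data$reject_mc_se
    ), width = 0.15) +
    ggplot2::geom_hline(yintercept = nominal, linetype = 2) +
    ggplot2::labs(x = "Analysis model",
                  y = if (cfg$effect_kind == "none") "Type I error (%)"
                      else "Power (%)") +
    ggplot2::theme_bw()
}
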