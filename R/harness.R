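# Six-step simulation loop: simulate an observational study, fit the
# observational random slopes model, size the trial from the estimates,
# simulate the trial, analyse it with the requested models, repeat.

#' Configure a simulation scenario
#'
#' Bundles everything one scenario of the simulation study needs. Defaults
#' follow the reference study conditions: a 1000-person observational
#' study with annual visits over 5 years, target effect and trial effect
#' rate \eqn{-0.05}/year when `sigma2_e = 0.15` and \eqn{-0.1}/year when
#' `sigma2_e = 2`, delayed-decline delay 1.25 years (2.5 with the larger
#' residual variance), 5% two-sided alpha and 80% target power.
#'
#' Observational-stage seeds are keyed only on (shape, residual variance,
#' replicate), so scenarios that differ only in their treatment-effect
#' kind share the identical sequence of observational studies and hence of
#' trial sample sizes.
#'
#' @param shape Trajectory shape, see [f_shape()].
#' @param effect_kind `"none"`, `"proportional_time"`,
#'   `"proportional_control_change"` or `"delayed_decline"`.
#' @param sigma2_e Residual variance of the generating mechanism.
#' @param gamma Trial effect rate; defaulted from `sigma2_e` as above.
#' @param delay Delay for `delayed_decline`; defaulted from `sigma2_e`.
#' @param vc_base Intercept/slope variance components of the generator
#'   (list with `sigma2_u0`, `sigma2_u1`, `sigma_u01`); defaults 0.5,
#'   0.01, \eqn{0.5\sqrt{0.005}}.
#' @param obs_schedule,trial_schedule Visit schedules in years.
#' @param n_obs Observational-study size.
#' @param d Target treatment effect for the sample-size formula
#'   (difference in slopes, outcome/year).
#' @param alpha,power_target Test level and target power.
#' @param n_reps Number of Monte-Carlo replicates.
#' @param base_seed Integer base seed for the scenario.
#' @param models Analysis models to fit to each trial: subset of
#'   `"rs"`, `"ltfc"`, `"fctfc"`, `"ftfc"`.
#' @param boundary_filter `"none"` or `"exclude_obs_boundary"` (drop
#'   replicates whose observational fit put the intercept-slope
#'   correlation on the boundary).
#' @return An object of class `scenario_config`.
#' @examples
#' scenario_config("steady", "proportional_time", n_reps = 10, base_seed = 1)
#' @export
scenario_config <- function(shape,
                            effect_kind = c("none", "proportional_time",
                                            "proportional_control_change",
                                            "delayed_decline"),
                            sigma2_e = 0.15,
                            gamma = NULL,
                            delay = NULL,
                            vc_base = list(sigma2_u0 = 0.5, sigma2_u1 = 0.01,
                                           sigma_u01 = 0.5 * sqrt(0.005)),
                            obs_schedule = 0:5,
                            trial_schedule = 0:5,
                            n_obs = 1000,
                            d = NULL,
                            alpha = 0.05,
                            power_target = 0.8,
                            n_reps = 500,
                            base_seed = 20231121,
                            models = c("rs", "ltfc", "ftfc"),
                            boundary_filter = c("none",
                                                "exclude_obs_boundary")) {
  shape <- match_shape(shape)
  effect_kind <- match.arg(effect_kind)
  boundary_filter <- match.arg(boundary_filter)
  models <- match.arg(models, c("rs", "ltfc", "fctfc", "ftfc"),
                      several.ok = TRUE)
  default_rate <- if (isTRUE(all.equal(sigma2_e, 2))) -0.1 else -0.05
  if (effect_kind %in% c("proportional_time",
                         "proportional_control_change") && is.null(gamma)) {
    gamma <- default_rate
  }
  if (effect_kind == "delayed_decline" && is.null(delay)) {
    delay <- if (isTRUE(all.equal(sigma2_e, 2))) 2.5 else 1.25
  }
  d <- d %||% default_rate
  if (effect_kind != "none" && !is.null(gamma) && sign(d) != sign(gamma)) {
    abort("`d` must have the same sign as `gamma` when there is a treatment effect.")
  }
  vc <- variance_components(vc_base$sigma2_u0, vc_base$sigma2_u1,
                            vc_base$sigma_u01, sigma2_e)
  effect <- switch(effect_kind,
    none = treatment_effect("none"),
    proportional_time = treatment_effect("proportional_time", gamma = gamma),
    proportional_control_change =
      treatment_effect("proportional_control_change", gamma = gamma),
    delayed_decline = treatment_effect("delayed_decline", delay = delay)
  )
  structure(list(
    shape = shape, effect_kind = effect_kind, effect = effect,
    gamma = gamma, delay = delay,
    sigma2_e = sigma2_e, vc = vc,
    obs_schedule = visit_schedule(obs_schedule),
    trial_schedule = visit_schedule(trial_schedule),
    n_obs = n_obs, d = d, alpha = alpha, power_target = power_target,
    n_reps = as.integer(n_reps), base_seed = as.integer(base_seed),
    models = models, boundary_filter = boundary_filter
  ), class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario>\n")
  cat("  shape:", x$shape, " effect:", x$effect_kind,
      if (!is.null(x$gamma)) paste0("(gamma ", x$gamma, ")"),
      if (!is.null(x$delay)) paste0("(delay ", x$delay, "y)"), "\n")
  cat("  sigma2_e:", x$sigma2_e, " trial:",
      tail(x$trial_schedule, 1), "years  d:", x$d, "\n")
  cat("  reps:", x$n_reps, " seed:", x$base_seed,
      " models:", paste(x$models, collapse = ","), "\n")
  invisible(x)
}

#' Run one replicate of the six-step loop
#'
#' Steps: (1) simulate the observational study; (2) fit the observational
#' random slopes model through the optimiser ladder; (3) size the trial
#' from the estimated variance components; (4) simulate the trial at that
#' size under the scenario's treatment effect; (5) fit each requested
#' analysis model and extract the final-visit treatment effect. All
#' randomness comes from child seeds derived from the scenario's base seed
#' and `rep_index`, so any replicate can be reproduced in isolation.
#'
#' @param config A [scenario_config()].
#' @param rep_index Replicate number (1-based).
#' @return A list with `rep_index`, `n_trial`, `obs` (observational-stage
#'   fit summary) and `estimates` (one tibble row per requested model).
#' @export
run_replicate <- function(config, rep_index) {
  stopifnot(inherits(config, "scenario_config"))
  obs_seed <- child_seed(config$base_seed, "obs", config$shape,
                         config$sigma2_e, rep_index)
  obs <- simulate_observational(config$shape, config$vc,
                                config$obs_schedule, config$n_obs,
                                seed = obs_seed)
  ofit <- fit_with_ladder(obs, "observational")
  obs_summary <- list(
    converged = ofit$converged,
    boundary = ofit$boundary,
    vc_hat = if (ofit$converged) unlist(ofit$vc_hat) else rep(NA_real_, 4),
    algorithm_used = ofit$algorithm_used
  )
  if (!ofit$converged) {
    return(list(rep_index = rep_index, n_trial = NA_integer_,
                obs = obs_summary, estimates = NULL))
  }
  n_trial <- slopes_sample_size(ofit$vc_hat, config$d,
                                config$trial_schedule, config$alpha,
                                config$power_target)
  n_trial <- max(n_trial, 4L)
  trial_seed <- child_seed(config$base_seed, "trial", config$shape,
                           config$sigma2_e, config$effect_kind,
                           config$gamma %||% 0, config$delay %||% 0,
                           config$trial_schedule, rep_index)
  trial <- simulate_trial(config$shape, config$effect, config$vc,
                          config$trial_schedule, n_trial,
                          seed = trial_seed)
  est <- purrr::map(config$models, function(mod) {
    fit <- if (mod == "rs") {
      fit_with_ladder(trial, "trial")
    } else {
      fit_marginal(trial, mod)
    }
    if (!fit$converged) {
      return(tibble::tibble(model = mod, effect_final = NA_real_,
                            se = NA_real_, df = NA_real_,
                            statistic = NA_real_, p_value = NA_real_,
                            reject = NA, gamma = NA_real_,
                            t_final = tail(config$trial_schedule, 1),
                            converged = FALSE, boundary = NA))
    }
    out <- final_time_effect(fit, config$alpha)
    out$converged <- TRUE
    out$boundary <- if (mod == "rs") fit$boundary else NA
    out
  })
  list(rep_index = rep_index, n_trial = n_trial, obs = obs_summary,
       estimates = dplyr::bind_rows(est))
}

#' Run a full scenario and summarise performance
#'
#' Executes [run_replicate()] `n_reps` times and aggregates the results
#' into per-model performance measures: convergence and boundary rates,
#' rejection rate (power, or type-I error under no effect) with its
#' Monte-Carlo SE, mean final-visit effect, mean per-year slope, empirical
#' SE (SD of effect estimates), mean model-based SE (root mean variance)
#' and the percentage bias of the model SE against the empirical SE.
#'
#' Rejection and estimation metrics are computed only over replicates in
#' which the observational fit and every requested trial model converged
#' (and, under `boundary_filter = "exclude_obs_boundary"`, whose
#' observational correlation stayed inside \eqn{\pm 0.99}); the exclusion
#' count is reported in the attributes.
#'
#' @inheritParams run_replicate
#' @param keep_reps Keep the per-replicate results as attribute `"reps"`.
#' @return A tibble of class `slopes_perf`, one row per model, with
#'   attributes `config`, `obs` (observational-stage summary) and
#'   optionally `reps`.
#' @examples
#' \donttest{
#' cfg <- scenario_config("steady", "proportional_time", n_reps = 20,
#'                        base_seed = 4)
#' run_scenario(cfg)
#' }
#' @export
run_scenario <- function(config, keep_reps = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  if (config$n_reps < 2) abort("`n_reps` must be at least 2.")
  reps <- purrr::map(seq_len(config$n_reps),
                     function(r) run_replicate(config, r))

  obs_conv <- vapply(reps, function(r) isTRUE(r$obs$converged), logical(1))
  obs_bound <- vapply(reps, function(r) isTRUE(r$obs$boundary), logical(1))
  if (!any(obs_conv)) abort("No replicate produced a converged observational fit.")

  usable <- obs_conv
  if (config$boundary_filter == "exclude_obs_boundary") {
    usable <- usable & !obs_bound
  }
  est <- dplyr::bind_rows(purrr::map(which(usable), function(i) {
    e <- reps[[i]]$estimates
    e$rep_index <- reps[[i]]$rep_index
    e$n_trial <- reps[[i]]$n_trial
    e
  }))
  if (nrow(est) == 0) abort("No usable replicates after filtering.")

  all_conv <- est |>
    dplyr::summarise(all_converged = all(.data$converged),
                     .by = "rep_index")
  good_reps <- all_conv$rep_index[all_conv$all_converged]

  summary <- est |>
    dplyr::summarise(
      n_reps_total = config$n_reps,
      n_reps_used = sum(.data$rep_index %in% good_reps),
      convergence_pct = 100 * mean(.data$converged),
      boundary_pct = if (all(is.na(.data$boundary))) NA_real_ else
        100 * mean(.data$boundary[.data$converged], na.rm = TRUE),
      reject_pct = 100 * mean(.data$reject[.data$rep_index %in% good_reps]),
      mean_effect = mean(.data$effect_final[.data$rep_index %in% good_reps]),
      mean_slope = mean(.data$gamma[.data$rep_index %in% good_reps]),
      empirical_se = sd(.data$effect_final[.data$rep_index %in% good_reps]),
      mean_model_se =
        sqrt(mean(.data$se[.data$rep_index %in% good_reps]^2)),
      mean_n_trial = mean(.data$n_trial),
      .by = "model"
    ) |>
    dplyr::mutate(
      reject_mc_se = mc_se(.data$reject_pct / 100, .data$n_reps_used),
      se_pct_bias = 100 * (.data$mean_model_se - .data$empirical_se) /
        .data$empirical_se
    ) |>
    dplyr::relocate("reject_mc_se", .after = "reject_pct")

  attr(summary, "config") <- config
  attr(summary, "obs") <- list(
    convergence_pct = 100 * mean(obs_conv),
    boundary_pct = 100 * mean(obs_bound[obs_conv]),
    n_excluded = config$n_reps - length(good_reps),
    mean_vc_hat = colMeans(do.call(rbind, purrr::map(
      reps[obs_conv], function(r) r$obs$vc_hat
    )))
  )
  if (keep_reps) attr(summary, "reps") <- reps
  class(summary) <- c("slopes_perf", class(summary))
  summary
}

#' Monte-Carlo standard error of an estimated proportion
#'
#' @param p Proportion in `[0, 1]`.
#' @param n_reps Number of Monte-Carlo replicates.
#' @return The MC standard error as a percentage,
#'   \eqn{100\sqrt{p(1-p)/n}}.
#' @examples
#' mc_se(0.8, 5000)  # 0.6 (1 dp)
#' @export
mc_se <- function(p, n_reps) {
  stopifnot(all(p >= 0 & p <= 1), all(n_reps >= 1))
  100 * sqrt(p * (1 - p) / n_reps)
}

#' 95% Monte-Carlo confidence bounds around a nominal rate
#'
#' The band of observed percentages whose 95% Monte-Carlo confidence
#' interval covers the nominal rate, as reported at a given printing
#' precision: \eqn{100p \pm 1.96 \times} (MC SE rounded to
#' `reported_dp`), with the bounds rounded to `reported_dp`.
#'
#' @param p_nominal Nominal proportion in `[0, 1]`.
#' @inheritParams mc_se
#' @param reported_dp Decimal places used when reporting (default 1).
#' @return Named numeric vector `c(lower, upper)` in percent.
#' @examples
#' mc_ci_bounds(0.05, 5000)  # 4.4, 5.6
#' mc_ci_bounds(0.8, 5000)   # 78.8, 81.2
#' @export
mc_ci_bounds <- function(p_nominal, n_reps, reported_dp = 1) {
  se_r <- round(mc_se(p_nominal, n_reps), reported_dp)
  c(lower = round(100 * p_nominal - 1.96 * se_r, reported_dp),
    upper = round(100 * p_nominal + 1.96 * se_r, reported_dp))
}

#' Percentage bias of the model-based standard error
#'
#' @param mean_model_se Square root of the mean model-based variance.
#' @param empirical_se Standard deviation of the effect estimates.
#' @return `100 * (mean_model_se - empirical_se) / empirical_se`.
#' @export
se_pct_bias <- function(mean_model_se, empirical_se) {
  if (any(empirical_se <= 0)) {
    abort("`empirical_se` must be positive.")
  }
  100 * (mean_model_se - empirical_se) / empirical_se
}

#' Build a factorial grid of scenarios
#'
#' Expands trajectory shapes, treatment-effect families, trial lengths and
#' residual variances into [scenario_config()] objects. The
#' `"nonproportional"` effect family maps to proportional-to-control-change
#' for the non-linear shapes and to delayed decline for the steady shape
#' (for which the two proportional effects coincide). The free
#' control-group trajectory model (`fctfc`) is added only to the steady /
#' proportional / 5-year / smaller-residual-variance cell, the one setting
#' where it is not redundant with the linear-trajectories model.
#'
#' @param shapes Trajectory shapes to include.
#' @param effects Subset of `"none"`, `"proportional"`, `"nonproportional"`.
#' @param trial_lengths Trial lengths in years (annual visits).
#' @param sigma2_e Residual variances to include.
#' @param n_reps,base_seed,models,boundary_filter Passed to
#'   [scenario_config()].
#' @return A tibble with descriptor columns and a `config` list-column.
#' @examples
#' grid <- build_grid(shapes = "steady", n_reps = 10)
#' nrow(grid)
#' @export
build_grid <- function(shapes = trajectory_shapes(),
                       effects = c("none", "proportional",
                                   "nonproportional"),
                       trial_lengths = c(5, 3),
                       sigma2_e = c(0.15, 2),
                       n_reps = 500,
                       base_seed = 20231121,
                       models = c("rs", "ltfc", "ftfc"),
                       boundary_filter = "none") {
  effects <- match.arg(effects, several.ok = TRUE)
  shapes <- vapply(shapes, match_shape, character(1))
  cells <- tidyr::expand_grid(shape = shapes, effect_family = effects,
                              trial_length = trial_lengths,
                              sigma2_e = sigma2_e)
  cells$effect_kind <- dplyr::case_when(
    cells$effect_family == "none" ~ "none",
    cells$effect_family == "proportional" ~ "proportional_time",
    cells$shape == "steady" ~ "delayed_decline",
    TRUE ~ "proportional_control_change"
  )
  cells$config <- purrr::pmap(
    list(cells$shape, cells$effect_kind, cells$trial_length, cells$sigma2_e),
    function(shape, kind, len, s2e) {
      mods <- models
      if (shape == "steady" && kind == "proportional_time" && len == 5 &&
          isTRUE(all.equal(s2e, 0.15)) && !"fctfc" %in% mods) {
        mods <- append(mods, "fctfc", after = match("ltfc", mods,
                                                    nomatch = 1))
      }
      scenario_config(shape, kind, sigma2_e = s2e,
                      trial_schedule = 0:len, n_reps = n_reps,
                      base_seed = base_seed, models = mods,
                      boundary_filter = boundary_filter)
    }
  )
  cells
}

#' Write and re-read a performance report
#'
#' `write_report()` binds one or more scenario summaries (adding scenario
#' descriptor columns from each summary's configuration) and writes a CSV
#' with a stable column set; `read_report()` parses it back.
#'
#' @param summaries A `slopes_perf` tibble or a list of them.
#' @param path File path for the CSV report.
#' @return `write_report()` returns the bound tibble invisibly;
#'   `read_report()` returns the parsed tibble.
#' @export
write_report <- function(summaries, path) {
  if (inherits(summaries, "slopes_perf")) summaries <- list(summaries)
  rows <- purrr::map(summaries, function(s) {
    cfg <- attr(s, "config")
    obs <- attr(s, "obs")
    out <- tibble::as_tibble(s)
    tibble::tibble(
      shape = cfg$shape,
      effect_kind = cfg$effect_kind,
      sigma2_e = cfg$sigma2_e,
      trial_length = tail(cfg$trial_schedule, 1),
      n_reps = cfg$n_reps,
      base_seed = cfg$base_seed,
      obs_convergence_pct = obs$convergence_pct,
      obs_boundary_pct = obs$boundary_pct,
      n_excluded = obs$n_excluded
    )[rep(1, nrow(out)), ] |> dplyr::bind_cols(out)
  })
  out <- dplyr::bind_rows(rows)
  readr::write_csv(out, path)
  invisible(out)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
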