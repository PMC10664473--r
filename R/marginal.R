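# Marginal models with unstructured covariance, fitted by iterated GLS.
#
# Three mean structures share one engine:
#   ltfc  "linear trajectories, free covariance":  y = b0 + b1 t + g z t
#   fctfc "free control-group trajectory, free covariance": y = b_j + g z t
#   ftfc  "free trajectories, free covariance":    y = b_j + g_j z, g_0 = 0
# All impose the randomisation constraint of a common baseline mean. The
# Gaussian MLE is found by alternating the GLS fixed-effect solve with the
# ML covariance update (average residual outer product, divisor N).

#' Fit a marginal model with unstructured covariance
#'
#' Fits one of three repeated-measures models in which each visit-pair
#' covariance is a free parameter, by iterating generalised least squares
#' for the fixed effects with the maximum-likelihood covariance update
#' until the log-likelihood is stationary. All three models constrain the
#' baseline mean to be equal in the two arms, as justified by
#' randomisation.
#'
#' @inheritParams reml_loglik_rs
#' @param model_kind `"ltfc"` (linear trajectories, free covariance),
#'   `"fctfc"` (free control-group trajectory, proportional-to-time
#'   treatment effect) or `"ftfc"` (free per-visit group means with zero
#'   baseline difference).
#' @param tol Relative log-likelihood change declaring the fixed point
#'   reached (default 1e-10).
#' @param max_iter Iteration budget (default 200); exhausting it returns a
#'   fit with `converged = FALSE`.
#' @return An object of class `slopes_marginal_fit` with elements
#'   `model_kind`, `coefficients`, `se`, `cov_fixed`, `sigma_hat`,
#'   `loglik`, `converged`, `iterations`, `df_resid`, `schedule`,
#'   `n_subjects`.
#' @seealso [final_time_effect()], [tidy.slopes_marginal_fit()]
#' @examples
#' trial <- simulate_trial("late", treatment_effect("proportional_time", -0.05),
#'                         n_total = 80, seed = 5)
#' fit <- fit_marginal(trial, "ftfc")
#' tail(coef(fit), 1)  # treatment effect at the final visit
#' @export
fit_marginal <- function(data, model_kind = c("ltfc", "fctfc", "ftfc"),
                         tol = 1e-10, max_iter = 200) {
  model_kind <- match.arg(model_kind)
  stats <- cohort_stats(data)
  if (length(stats$arms) < 2) {
    abort("Marginal models need a two-arm dataset.")
  }
  if (model_kind %in% c("ltfc",
                        "rs_trial") && length(unique(stats$times)) < 2) {
    abort("At least two distinct visit times are required.")
  }
  Xs <- lapply(stats$arms, function(a) arm_design(model_kind, stats$times,
                                                  a$arm))

  # start: OLS fixed effects (identity working covariance), then the
  # residual scatter as the first unstructured covariance
  Sigma <- diag(stats$nv)
  g <- gls_pieces(stats, Xs, Sigma)
  Sigma <- g$S / stats$N
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0
  repeat {
    iter <- iter + 1
    v <- ml_value(stats, Xs, Sigma)
    if (is.null(v)) break
    Sigma_new <- v$gls$S / stats$N
    if (is.finite(ll_old) &&
        abs(v$ll - ll_old) <= tol * (1 + abs(v$ll))) {
      converged <- TRUE
      g <- v$gls
      ll_old <- v$ll
      break
    }
    ll_old <- v$ll
    g <- v$gls
    Sigma <- Sigma_new
    if (iter >= max_iter) break
  }

  beta <- drop(g$beta)
  names(beta) <- design_colnames(model_kind, stats$times)
  se <- sqrt(pmax(diag(g$cov_beta), 0))
  names(se) <- names(beta)
  dimnames(g$cov_beta) <- list(names(beta), names(beta))
  dimnames(Sigma) <- list(paste0("t", stats$times), paste0("t", stats$times))

  structure(list(
    model_kind = model_kind,
    coefficients = beta, se = se,
    cov_fixed = g$cov_beta,
    sigma_hat = Sigma,
    loglik = ll_old,
    converged = converged, iterations = iter,
    # residual df: subjects minus the rank of the between-subject design
    # (intercept + arm)
    df_resid = as.integer(stats$N - 2),
    schedule = stats$times, n_subjects = stats$N
  ), class = "slopes_marginal_fit")
}

#' @export
coef.slopes_marginal_fit <- function(object, ...) object$coefficients

#' @export
print.slopes_marginal_fit <- function(x, ...) {
  label <- c(ltfc = "linear trajectories, free covariance",
             fctfc = "free control-group trajectory, free covariance",
             ftfc = "free trajectories, free covariance")[x$model_kind]
  cat("<marginal fit:", label, ">\n")
  cat("  subjects:", x$n_subjects, " visits:", length(x$schedule),
      " converged:", x$converged, "(", x$iterations, "iterations )\n")
  print(round(cbind(estimate = x$coefficients, std.error = x$se), 5))
  cat("  log-likelihood:", format(x$loglik), "\n")
  invisible(x)
}

#' Treatment effect at the final visit
#'
#' Extracts the common estimand — the treated-minus-control difference in
#' mean outcome at the last scheduled visit — from any fitted analysis
#' model, with its standard error and a two-sided Wald test. For
#' slope-parameterised models (random slopes, LTFC, FCTFC) the slope
#' difference \eqn{\hat\gamma} and its SE are multiplied by the follow-up
#' time; for the free-trajectories model the final-visit group difference
#' is a model coefficient with its own SE.
#'
#' The test reference is a t distribution: Satterthwaite-style degrees of
#' freedom for the random slopes fit, residual degrees of freedom
#' (subjects minus between-subject design rank) for the marginal fits.
#'
#' @param fit A `slopes_rs_fit` (trial design) or `slopes_marginal_fit`.
#' @param alpha Two-sided test level (default 0.05).
#' @return A one-row tibble with columns `model`, `effect_final`, `se`,
#'   `df`, `statistic`, `p_value`, `reject`, `gamma` (per-year slope
#'   difference; `NA` for the free-trajectories model) and `t_final`.
#' @examples
#' trial <- simulate_trial("steady", treatment_effect("proportional_time", -0.05),
#'                         n_total = 300, seed = 11)
#' final_time_effect(fit_random_slopes(trial, "trial"))
#' @export
final_time_effect <- function(fit, alpha = 0.05) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha > 0, alpha < 1)
  if (inherits(fit, "slopes_rs_fit")) {
    if (!fit$converged) abort("Cannot extract an estimand from a non-converged fit.")
    if (fit$design != "trial") {
      abort("The estimand is defined for trial fits (no gamma in the observational model).")
    }
    t_final <- tail(fit$schedule, 1)
    eff <- fit$gamma * t_final
    se <- fit$se_gamma * t_final
    df <- fit$df_gamma
    if (!is.finite(df)) df <- fit$n_subjects - 2
    model <- "rs"
    gamma <- fit$gamma
  } else if (inherits(fit, "slopes_marginal_fit")) {
    if (!fit$converged) abort("Cannot extract an estimand from a non-converged fit.")
    t_final <- tail(fit$schedule, 1)
    df <- fit$df_resid
    model <- fit$model_kind
    if (fit$model_kind %in% c("ltfc", "fctfc")) {
      gamma <- unname(fit$coefficients["gamma"])
      eff <- gamma * t_final
      se <- unname(fit$se["gamma"]) * t_final
    } else {
      nm <- paste0("gamma_t", t_final)
      eff <- unname(fit$coefficients[nm])
      se <- unname(fit$se[nm])
      gamma <- NA_real_
    }
  } else {
    abort("`fit` must be a slopes_rs_fit or slopes_marginal_fit.")
  }
  statistic <- if (se > 0) eff / se else NA_real_
  p <- if (is.finite(statistic)) 2 * pt(-abs(statistic), df = df) else NA_real_
  tibble::tibble(
    model = model,
    effect_final = eff, se = se, df = df,
    statistic = statistic, p_value = p,
    reject = is.finite(p) && p < alpha,
    gamma = gamma, t_final = t_final
  )
}
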