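# broom-style accessors for fitted objects

#' Tidy a random slopes fit
#'
#' @param x A `slopes_rs_fit`.
#' @param effects `"fixed"`, `"ran_pars"` or both.
#' @param ... Unused.
#' @return A tibble with columns `effect`, `term`, `estimate`,
#'   `std.error`.
#' @examples
#' obs <- simulate_observational("steady", n_subjects = 100, seed = 1)
#' tidy(fit_random_slopes(obs, "observational"))
#' @export
tidy.slopes_rs_fit <- function(x, effects = c("fixed", "ran_pars"), ...) {
  effects <- match.arg(effects, several.ok = TRUE)
  out <- list()
  if ("fixed" %in% effects) {
    out$fixed <- tibble::tibble(
      effect = "fixed",
      term = names(x$beta),
      estimate = unname(x$beta),
      std.error = unname(x$se)
    )
  }
  if ("ran_pars" %in% effects) {
    out$ran <- tibble::tibble(
      effect = "ran_pars",
      term = names(x$vc_se),
      estimate = unname(unlist(x$vc_hat)),
      std.error = unname(x$vc_se)
    )
  }
  dplyr::bind_rows(out)
}

#' Glance at a random slopes fit
#'
#' @inheritParams tidy.slopes_rs_fit
#' @return A one-row tibble with fit-level summaries.
#' @export
glance.slopes_rs_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik_reml,
    converged = x$converged,
    boundary = x$boundary,
    algorithm = x$algorithm_used,
    n_subjects = x$n_subjects,
    n_visits = length(x$schedule),
    design = x$design
  )
}

#' Tidy a marginal (unstructured-covariance) fit
#'
#' @param x A `slopes_marginal_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`.
#' @export
tidy.slopes_marginal_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$se)
  )
}

#' Glance at a marginal fit
#'
#' @inheritParams tidy.slopes_marginal_fit
#' @return A one-row tibble with fit-level summaries.
#' @export
glance.slopes_marginal_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik,
    converged = x$converged,
    iterations = x$iterations,
    model_kind = x$model_kind,
    n_subjects = x$n_subjects,
    n_visits = length(x$schedule),
    df.residual = x$df_resid
  )
}
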