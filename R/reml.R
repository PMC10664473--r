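# Random slopes model: constrained REML on balanced complete long data.
#
# Balance is exploited throughout: with a common visit schedule and
# arm-dependent fixed-effect design, the restricted likelihood depends on
# the data only through per-arm counts, per-arm visit-mean vectors and
# per-arm raw scatter matrices, so each likelihood evaluation costs
# O(n_visits^3) regardless of the number of subjects.

# ---- sufficient statistics ------------------------------------------------

# Validate a long dataset (subject_id, arm, time, y) and reduce it to
# per-arm sufficient statistics.
cohort_stats <- function(data) {
  req <- c("subject_id", "arm", "time", "y")
  if (!all(req %in% names(data))) {
    abort("Data must have columns subject_id, arm, time, y.")
  }
  d <- dplyr::arrange(dplyr::as_tibble(data), .data$subject_id, .data$time)
  times <- sort(unique(d$time))
  nv <- length(times)
  if (nv < 2) abort("At least 2 distinct visit times are required.")
  n_total <- nrow(d) / nv
  if (n_total != floor(n_total)) {
    abort("Data are not balanced: row count is not a multiple of the number of visits.")
  }
  if (!all(d$time == rep(times, n_total))) {
    abort("Data are not complete: every subject needs exactly one record per visit.")
  }
  if (anyNA(d$y)) abort("Missing outcome values are not supported.")
  arm_subj <- d$arm[seq(1, nrow(d), by = nv)]
  if (!all(d$arm == rep(arm_subj, each = nv))) {
    abort("`arm` must be constant within subject.")
  }
  if (!all(arm_subj %in% c(0, 1))) abort("`arm` must be coded 0/1.")
  Y <- matrix(d$y, nrow = nv)  # visits x subjects
  arms <- lapply(sort(unique(arm_subj)), function(a) {
    Ya <- Y[, arm_subj == a, drop = FALSE]
    list(arm = a, n = ncol(Ya), m = rowMeans(Ya), C = tcrossprod(Ya))
  })
  list(times = times, nv = nv, N = as.integer(n_total), arms = arms, Y = Y,
       arm_subj = arm_subj)
}

# Fixed-effect design matrix for one arm over the common schedule.
arm_design <- function(kind, times, arm) {
  nv <- length(times)
  switch(kind,
    rs_obs = cbind(`(Intercept)` = 1, time = times),
    rs_trial = cbind(`(Intercept)` = 1, time = times, `arm:time` = arm * times),
    ltfc = cbind(`(Intercept)` = 1, time = times, `arm:time` = arm * times),
    fctfc = cbind(diag(nv), `arm:time` = arm * times),
    ftfc = cbind(diag(nv),
                 (if (nv > 1) arm * diag(nv)[, -1, drop = FALSE] else NULL)),
    abort("Unknown design kind.")
  )
}

design_colnames <- function(kind, times) {
  nv <- length(times)
  switch(kind,
    rs_obs = c("beta0", "beta1"),
    rs_trial = c("beta0", "beta1", "gamma"),
    ltfc = c("beta0", "beta1", "gamma"),
    fctfc = c(paste0("beta_t", times), "gamma"),
    ftfc = c(paste0("beta_t", times), paste0("gamma_t", times[-1]))
  )
}

# GLS fixed effects + Gaussian quadratic form given a per-person covariance.
# Returns NULL if Sigma is not positive definite.
gls_pieces <- function(stats, Xs, Sigma) {
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  Sinv <- chol2inv(ch)
  logdet <- 2 * sum(log(diag(ch)))
  p <- ncol(Xs[[1]])
  A <- matrix(0, p, p)
  b <- numeric(p)
  for (i in seq_along(stats$arms)) {
    a <- stats$arms[[i]]
    XtS <- crossprod(Xs[[i]], Sinv)
    A <- A + a$n * (XtS %*% Xs[[i]])
    b <- b + a$n * (XtS %*% a$m)
  }
  cov_beta <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(cov_beta)) return(NULL)
  beta <- drop(cov_beta %*% b)
  S <- matrix(0, stats$nv, stats$nv)
  for (i in seq_along(stats$arms)) {
    a <- stats$arms[[i]]
    mu <- drop(Xs[[i]] %*% beta)
    S <- S + a$C - a$n * (tcrossprod(a$m, mu) + tcrossprod(mu, a$m)) +
      a$n * tcrossprod(mu)
  }
  quad <- sum(Sinv * S)
  list(beta = beta, cov_beta = cov_beta, A = A, quad = quad,
       logdet = logdet, Sinv = Sinv, S = S)
}

reml_value <- function(stats, Xs, Sigma) {
  g <- gls_pieces(stats, Xs, Sigma)
  if (is.null(g)) return(NULL)
  p <- ncol(Xs[[1]])
  n <- stats$N * stats$nv
  ldA <- determinant(g$A, logarithm = TRUE)
  if (ldA$sign <= 0) return(NULL)
  ll <- -0.5 * ((n - p) * log(2 * pi) + stats$N * g$logdet +
                  as.numeric(ldA$modulus) + g$quad)
  list(ll = ll, gls = g)
}

ml_value <- function(stats, Xs, Sigma) {
  g <- gls_pieces(stats, Xs, Sigma)
  if (is.null(g)) return(NULL)
  n <- stats$N * stats$nv
  ll <- -0.5 * (n * log(2 * pi) + stats$N * g$logdet + g$quad)
  list(ll = ll, gls = g)
}

#' Restricted log-likelihood of the random slopes model
#'
#' Evaluates the REML criterion of the random slopes model at a given set
#' of [variance_components()], with the fixed effects profiled out by
#' generalised least squares. The marginal per-person covariance has entries
#' \eqn{\sigma^2_{u0} + t_j t_k \sigma^2_{u1} + (t_j + t_k)\sigma_{u01} +
#' 1\{j = k\}\sigma^2_e}.
#'
#' @param data Balanced, complete long data with columns `subject_id`,
#'   `arm`, `time`, `y`.
#' @param vc A [variance_components()] object.
#' @param design `"trial"` (fixed effects \eqn{\beta_0, \beta_1, \gamma})
#'   or `"observational"` (\eqn{\beta_0, \beta_1} only).
#' @return The restricted log-likelihood (a scalar).
#' @examples
#' obs <- simulate_observational("steady", n_subjects = 20, seed = 1)
#' reml_loglik_rs(obs, variance_components(), "observational")
#' @export
reml_loglik_rs <- function(data, vc, design = c("trial", "observational")) {
  design <- match.arg(design)
  vc <- as_variance_components(vc)
  stats <- cohort_stats(data)
  kind <- if (design == "trial") "rs_trial" else "rs_obs"
  Xs <- lapply(stats$arms, function(a) arm_design(kind, stats$times, a$arm))
  Sigma <- sigma_person(vc, stats$times)
  v <- reml_value(stats, Xs, Sigma)
  if (is.null(v)) {
    abort("Covariance is singular at this parameter point.")
  }
  v$ll
}

# ---- optimisation parameterisation ---------------------------------------

RHO_CLAMP <- 0.999

vc_from_theta <- function(theta) {
  theta <- pmin(pmax(theta, -30), 30)
  s0 <- exp(theta[1])
  s1 <- exp(theta[2])
  rho <- max(min(tanh(theta[3]), RHO_CLAMP), -RHO_CLAMP)
  se <- exp(theta[4])
  c(sigma2_u0 = s0, sigma2_u1 = s1, sigma_u01 = rho * sqrt(s0 * s1),
    sigma2_e = se)
}

theta_from_vc <- function(v) {
  s0 <- max(v[["sigma2_u0"]], 1e-8)
  s1 <- max(v[["sigma2_u1"]], 1e-8)
  rho <- v[["sigma_u01"]] / sqrt(s0 * s1)
  rho <- max(min(rho, RHO_CLAMP), -RHO_CLAMP)
  c(log(s0), log(s1), atanh(rho), log(max(v[["sigma2_e"]], 1e-8)))
}

# Method-of-moments starting values from per-subject least-squares lines.
mom_start <- function(stats) {
  t <- stats$times
  nv <- stats$nv
  tbar <- mean(t)
  stt <- sum((t - tbar)^2)
  w <- (t - tbar) / stt              # slope functional
  v <- rep(1 / nv, nv) - tbar * w    # intercept functional
  Spool <- matrix(0, nv, nv)
  for (a in stats$arms) {
    Spool <- Spool + a$C - a$n * tcrossprod(a$m)
  }
  Spool <- Spool / max(stats$N - length(stats$arms), 1)
  H <- cbind(1, t) %*% solve(crossprod(cbind(1, t)), t(cbind(1, t)))
  se0 <- max(sum(diag((diag(nv) - H) %*% Spool)) / max(nv - 2, 1), 1e-4)
  var_b <- drop(t(w) %*% Spool %*% w)
  var_a <- drop(t(v) %*% Spool %*% v)
  cov_ab <- drop(t(v) %*% Spool %*% w)
  s1 <- max(var_b - se0 * sum(w^2), 1e-6)
  s0 <- max(var_a - se0 * sum(v^2), 1e-6)
  rho <- cov_ab / sqrt(s0 * s1)
  rho <- max(min(rho, 0.9), -0.9)
  c(log(s0), log(s1), atanh(rho), log(se0))
}

num_gradient <- function(fn, x, h = NULL) {
  h <- h %||% pmax(1e-5 * abs(x), 1e-6)
  vapply(seq_along(x), function(k) {
    e <- numeric(length(x)); e[k] <- h[k]
    (fn(x + e) - fn(x - e)) / (2 * h[k])
  }, numeric(1))
}

num_hessian <- function(fn, x, h = NULL) {
  h <- h %||% pmax(1e-4 * abs(x), 1e-5)
  p <- length(x)
  H <- matrix(NA_real_, p, p)
  f0 <- fn(x)
  for (i in seq_len(p)) {
    ei <- numeric(p); ei[i] <- h[i]
    H[i, i] <- (fn(x + ei) - 2 * f0 + fn(x - ei)) / h[i]^2
    if (i < p) for (j in (i + 1):p) {
      ej <- numeric(p); ej[j] <- h[j]
      H[i, j] <- H[j, i] <-
        (fn(x + ei + ej) - fn(x + ei - ej) - fn(x - ei + ej) +
           fn(x - ei - ej)) / (4 * h[i] * h[j])
    }
  }
  H
}

# ---- fitting --------------------------------------------------------------

#' Fit the random slopes model by constrained REML
#'
#' Maximises the restricted likelihood of the random slopes model over the
#' valid variance-component region. Optimisation runs on the transformed
#' scale (log-variances, atanh intercept-slope correlation with the
#' correlation clamped to \eqn{\pm 0.999}), so the "correlation on the
#' boundary" state is an ordinary interior point of the search space and is
#' reported through the `boundary` flag (fired when the back-transformed
#' correlation magnitude exceeds 0.99). Fixed effects are obtained by GLS
#' at the optimum, with standard errors from \eqn{(X^T\hat\Sigma^{-1}X)^{-1}}.
#'
#' By default a pre-specified ladder of optimisers is worked through until
#' one converges (see [fit_with_ladder()]); non-convergence is recorded in
#' the returned object, never raised as an error.
#'
#' @inheritParams reml_loglik_rs
#' @param method `"ladder"` (default) or a single rung: `"bfgs"`,
#'   `"nelder-mead"`, `"bfgs-diag"` (quasi-Newton from a start with the
#'   intercept-slope covariance zeroed).
#' @param start Optional starting [variance_components()].
#' @return An object of class `slopes_rs_fit` with elements `beta`
#'   (named fixed effects), `se` (their SEs), `gamma`, `se_gamma`,
#'   `df_gamma` (Satterthwaite-style), `vc_hat`, `vc_se`, `converged`,
#'   `boundary`, `algorithm_used`, `loglik_reml`, `schedule`,
#'   `n_subjects`, `design`.
#' @seealso [fit_with_ladder()], [final_time_effect()], [tidy.slopes_rs_fit()]
#' @examples
#' trial <- simulate_trial("steady", treatment_effect("proportional_time", -0.05),
#'                         n_total = 60, seed = 2)
#' fit <- fit_random_slopes(trial, "trial")
#' fit$gamma
#' @export
fit_random_slopes <- function(data, design = c("trial", "observational"),
                              method = c("ladder", "bfgs", "nelder-mead",
                                         "bfgs-diag"),
                              start = NULL) {
  design <- match.arg(design)
  method <- match.arg(method)
  stats <- cohort_stats(data)
  kind <- if (design == "trial") "rs_trial" else "rs_obs"
  if (design == "trial" && length(stats$arms) < 2) {
    abort("A trial fit needs both arms present.")
  }
  Xs <- lapply(stats$arms, function(a) arm_design(kind, stats$times, a$arm))

  negll <- function(theta) {
    v <- vc_from_theta(theta)
    Sigma <- sigma_person_(v, stats$times)
    r <- reml_value(stats, Xs, Sigma)
    if (is.null(r) || !is.finite(r$ll)) return(1e10)
    -r$ll
  }

  th0 <- if (is.null(start)) mom_start(stats) else {
    s <- as_variance_components(start)
    theta_from_vc(unlist(s))
  }

  rungs <- switch(method,
    ladder = c("bfgs", "nelder-mead", "bfgs-diag"),
    method
  )
  fit_opt <- NULL
  used <- NA_character_
  th_prev <- th0
  for (rung in rungs) {
    res <- run_rung(negll, rung, th0, th_prev)
    th_prev <- res$par
    if (rung_converged(negll, res)) {
      fit_opt <- res
      used <- rung
      break
    }
  }

  converged <- !is.null(fit_opt)
  theta_hat <- if (converged) fit_opt$par else th_prev
  vhat <- vc_from_theta(theta_hat)
  vc_hat <- variance_components(vhat[["sigma2_u0"]], vhat[["sigma2_u1"]],
                                vhat[["sigma_u01"]], vhat[["sigma2_e"]])
  rho_hat <- vc_correlation(vc_hat)
  boundary <- converged && is.finite(rho_hat) && abs(rho_hat) > 0.99

  Sigma_hat <- sigma_person_(vhat, stats$times)
  piece <- reml_value(stats, Xs, Sigma_hat)
  beta <- drop(piece$gls$beta)
  names(beta) <- design_colnames(kind, stats$times)
  se <- sqrt(pmax(diag(piece$gls$cov_beta), 0))
  names(se) <- names(beta)

  vc_se <- rep(NA_real_, 4)
  df_gamma <- NA_real_
  if (converged) {
    inf <- vc_information(stats, Xs, vhat)
    vc_se <- inf$vc_se
    if (design == "trial") {
      df_gamma <- satterthwaite_df(stats, Xs, vhat, inf$vcov_vc,
                                   fallback = stats$N - 2)
    }
  }

  structure(list(
    beta = beta, se = se,
    gamma = if (design == "trial") unname(beta["gamma"]) else NULL,
    se_gamma = if (design == "trial") unname(se["gamma"]) else NULL,
    df_gamma = df_gamma,
    vc_hat = vc_hat,
    vc_se = setNames(vc_se, c("sigma2_u0", "sigma2_u1", "sigma_u01",
                              "sigma2_e")),
    converged = converged, boundary = boundary,
    algorithm_used = used,
    loglik_reml = if (converged) -fit_opt$value else NA_real_,
    schedule = stats$times, n_subjects = stats$N,
    design = design
  ), class = "slopes_rs_fit")
}

run_rung <- function(negll, rung, th0, th_prev) {
  switch(rung,
    bfgs = optim(th0, negll, method = "BFGS",
                 control = list(maxit = 300, reltol = 1e-12,
                                ndeps = rep(1e-5, length(th0)))),
    `nelder-mead` = optim(th_prev, negll, method = "Nelder-Mead",
                          control = list(maxit = 3000, reltol = 1e-12)),
    `bfgs-diag` = {
      start <- th0
      start[3] <- 0  # diagonal random-effects covariance start
      optim(start, negll, method = "BFGS",
            control = list(maxit = 300, reltol = 1e-12,
                           ndeps = rep(1e-5, length(th0))))
    },
    abort("Unknown optimiser rung.")
  )
}

# Declare convergence when the optimiser reports success and the
# central-difference score is negligible relative to the criterion value.
rung_converged <- function(negll, res) {
  if (res$convergence != 0 || !is.finite(res$value) || res$value >= 1e10) {
    return(FALSE)
  }
  g <- tryCatch(num_gradient(negll, res$par), error = function(e) NA)
  all(is.finite(g)) && max(abs(g)) <= 1e-4 * (1 + abs(res$value))
}

# Observed information of the REML criterion in the natural variance
# parameters; returns SEs of the variance-component estimates and their
# covariance matrix (NULL when the Hessian is not usable).
vc_information <- function(stats, Xs, vhat) {
  nll_nat <- function(v) {
    Sigma <- sigma_person_(c(sigma2_u0 = v[1], sigma2_u1 = v[2],
                             sigma_u01 = v[3], sigma2_e = v[4]), stats$times)
    r <- reml_value(stats, Xs, Sigma)
    if (is.null(r)) return(NA_real_)
    -r$ll
  }
  v0 <- unname(vhat)
  H <- tryCatch(num_hessian(nll_nat, v0), error = function(e) NULL)
  if (is.null(H) || anyNA(H)) {
    return(list(vc_se = rep(NA_real_, 4), vcov_vc = NULL))
  }
  W <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(W)) return(list(vc_se = rep(NA_real_, 4), vcov_vc = NULL))
  se <- sqrt(pmax(diag(W), 0))
  list(vc_se = se, vcov_vc = W)
}

# Satterthwaite-style degrees of freedom for the treatment-slope contrast:
# df = 2 V^2 / (g' W g), with V the GLS variance of gamma-hat as a function
# of the variance components, g its gradient and W the REML covariance of
# the variance-component estimates.
satterthwaite_df <- function(stats, Xs, vhat, vcov_vc, fallback) {
  if (is.null(vcov_vc)) return(fallback)
  vfun <- function(v) {
    Sigma <- sigma_person_(c(sigma2_u0 = v[1], sigma2_u1 = v[2],
                             sigma_u01 = v[3], sigma2_e = v[4]), stats$times)
    g <- gls_pieces(stats, Xs, Sigma)
    if (is.null(g)) return(NA_real_)
    p <- ncol(Xs[[1]])
    g$cov_beta[p, p]
  }
  v0 <- unname(vhat)
  V <- vfun(v0)
  g <- tryCatch(num_gradient(vfun, v0), error = function(e) NA)
  if (!all(is.finite(g)) || !is.finite(V) || V <= 0) return(fallback)
  denom <- drop(t(g) %*% vcov_vc %*% g)
  if (!is.finite(denom) || denom <= 0) return(fallback)
  df <- 2 * V^2 / denom
  if (!is.finite(df) || df <= 1) fallback else min(df, 1e7)
}

#' GLS fixed effects at a known covariance
#'
#' Solves \eqn{\hat\beta = (X^T\Sigma^{-1}X)^{-1}X^T\Sigma^{-1}Y} for the
#' random slopes mean structure with the per-person covariance built from
#' fixed, known [variance_components()] — no variance estimation. When the
#' observed means lie exactly in the model space the fixed effects are
#' recovered exactly, whatever covariance is supplied.
#'
#' @inheritParams reml_loglik_rs
#' @return A list with `beta` (named fixed effects) and `se` (their GLS
#'   standard errors at the supplied covariance).
#' @export
gls_fixed_effects <- function(data, vc, design = c("trial", "observational")) {
  design <- match.arg(design)
  vc <- as_variance_components(vc)
  stats <- cohort_stats(data)
  kind <- if (design == "trial") "rs_trial" else "rs_obs"
  Xs <- lapply(stats$arms, function(a) arm_design(kind, stats$times, a$arm))
  g <- gls_pieces(stats, Xs, sigma_person_(unlist(vc), stats$times))
  if (is.null(g)) abort("Covariance is singular at this parameter point.")
  beta <- drop(g$beta)
  names(beta) <- design_colnames(kind, stats$times)
  list(beta = beta, se = setNames(sqrt(pmax(diag(g$cov_beta), 0)),
                                  names(beta)))
}

#' Fit the random slopes model through the optimiser ladder
#'
#' Works through a fixed, pre-specified ordering of optimisation
#' algorithms until one converges: (1) quasi-Newton (BFGS) on the
#' transformed scale from method-of-moments starting values; (2) a
#' Nelder-Mead restart from wherever rung 1 stopped; (3) quasi-Newton from
#' a start with the intercept-slope covariance zeroed. The returned fit
#' records which rung succeeded in `algorithm_used`; if no rung converges
#' the fit is returned with `converged = FALSE`.
#'
#' @inheritParams fit_random_slopes
#' @return A `slopes_rs_fit`, see [fit_random_slopes()].
#' @export
fit_with_ladder <- function(data, design = c("trial", "observational")) {
  fit_random_slopes(data, design, method = "ladder")
}

#' @export
print.slopes_rs_fit <- function(x, ...) {
  cat("<random slopes fit (REML)>\n")
  cat("  design:", x$design, " subjects:", x$n_subjects,
      " visits:", length(x$schedule), "\n")
  cat("  converged:", x$converged,
      if (x$converged) paste0("(", x$algorithm_used, ")") else "",
      " boundary:", x$boundary, "\n")
  co <- cbind(estimate = x$beta, std.error = x$se)
  print(round(co, 5))
  v <- unlist(x$vc_hat)
  cat("  variance components:\n")
  print(round(v, 5))
  cat("  REML log-likelihood:", format(x$loglik_reml), "\n")
  invisible(x)
}
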