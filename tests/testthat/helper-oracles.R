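# Independent brute-force oracles used to validate the package's fast
# engines on small fixtures. These deliberately build the full joint
# covariance / optimise all parameters numerically rather than exploiting
# the balanced structure the package engines rely on.

# REML log-likelihood built from the full N*n_visits joint covariance.
naive_reml_loglik <- function(data, vc, design) {
  d <- dplyr::arrange(data, subject_id, time)
  times <- sort(unique(d$time))
  nv <- length(times)
  N <- nrow(d) / nv
  S <- outer(times, times, function(a, b) {
    vc$sigma2_u0 + a * b * vc$sigma2_u1 + (a + b) * vc$sigma_u01
  }) + diag(vc$sigma2_e, nv)
  V <- kronecker(diag(N), S)
  X <- if (design == "trial") {
    cbind(1, d$time, d$arm * d$time)
  } else {
    cbind(1, d$time)
  }
  y <- d$y
  Vi <- solve(V)
  A <- t(X) %*% Vi %*% X
  beta <- solve(A, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  n <- length(y)
  p <- ncol(X)
  as.numeric(-0.5 * ((n - p) * log(2 * pi) +
                       determinant(V)$modulus +
                       determinant(A)$modulus +
                       t(r) %*% Vi %*% r))
}

# Closed-form restricted likelihood of the i.i.d. Gaussian linear model
# (what the random-slopes REML criterion must reduce to when all random
# effects are zero).
iid_reml_loglik <- function(data, sigma2_e, design) {
  d <- dplyr::arrange(data, subject_id, time)
  X <- if (design == "trial") {
    cbind(1, d$time, d$arm * d$time)
  } else {
    cbind(1, d$time)
  }
  y <- d$y
  n <- length(y)
  p <- ncol(X)
  rss <- sum(stats::lm.fit(X, y)$residuals^2)
  -0.5 * ((n - p) * log(2 * pi) + (n - p) * log(sigma2_e) +
            determinant(crossprod(X))$modulus[1] + rss / sigma2_e)
}

# Gaussian ML log-likelihood of a marginal model at given fixed effects
# and per-person covariance.
marginal_ml_loglik <- function(data, kind, beta, Sigma) {
  d <- dplyr::arrange(data, subject_id, time)
  times <- sort(unique(d$time))
  nv <- length(times)
  N <- nrow(d) / nv
  Y <- matrix(d$y, nrow = nv)
  arm <- d$arm[seq(1, nrow(d), by = nv)]
  Xa <- function(a) marginal_design(kind, times, a)
  Si <- solve(Sigma)
  quad <- 0
  for (i in seq_len(N)) {
    r <- Y[, i] - Xa(arm[i]) %*% beta
    quad <- quad + drop(t(r) %*% Si %*% r)
  }
  -0.5 * (N * nv * log(2 * pi) +
            N * determinant(Sigma)$modulus[1] + quad)
}

marginal_design <- function(kind, times, a) {
  nv <- length(times)
  switch(kind,
    ltfc = cbind(1, times, a * times),
    fctfc = cbind(diag(nv), a * times),
    ftfc = cbind(diag(nv), a * diag(nv)[, -1, drop = FALSE])
  )
}

# Brute-force marginal MLE: generic numerical optimisation over the fixed
# effects and the Cholesky factor of the unstructured covariance.
brute_force_marginal_mle <- function(data, kind) {
  d <- dplyr::arrange(data, subject_id, time)
  times <- sort(unique(d$time))
  nv <- length(times)
  N <- nrow(d) / nv
  Y <- matrix(d$y, nrow = nv)
  arm <- d$arm[seq(1, nrow(d), by = nv)]
  p <- ncol(marginal_design(kind, times, 1))

  chol_from_par <- function(l) {
    L <- matrix(0, nv, nv)
    L[lower.tri(L, diag = TRUE)] <- l
    diag(L) <- exp(diag(L))
    L
  }
  negll <- function(par) {
    beta <- par[1:p]
    L <- chol_from_par(par[-(1:p)])
    Sigma <- L %*% t(L)
    ll <- tryCatch(marginal_ml_loglik(data, kind, beta, Sigma),
                   error = function(e) NA_real_)
    if (!is.finite(ll)) 1e10 else -ll
  }

  # start: OLS fixed effects, residual-scatter covariance
  X <- do.call(rbind, lapply(arm, function(a) marginal_design(kind, times, a)))
  b0 <- stats::lm.fit(X, d$y)$coefficients
  R <- matrix(d$y - X %*% b0, nrow = nv)
  S0 <- tcrossprod(R) / N + diag(1e-4, nv)
  L0 <- t(chol(S0))
  diag(L0) <- log(diag(L0))
  par0 <- c(b0, L0[lower.tri(L0, diag = TRUE)])

  o <- stats::optim(par0, negll, method = "BFGS",
                    control = list(maxit = 2000, reltol = 1e-15))
  o <- stats::optim(o$par, negll, method = "Nelder-Mead",
                    control = list(maxit = 20000, reltol = 1e-15))
  -o$value
}

# Generic stacked-GLS variance oracle for the 2-person trial: plain
# solve() on the full 2 n_v system, no Cholesky shortcuts.
stacked_gls_var_oracle <- function(vc, times) {
  nv <- length(times)
  S <- outer(times, times, function(a, b) {
    vc$sigma2_u0 + a * b * vc$sigma2_u1 + (a + b) * vc$sigma_u01
  }) + diag(vc$sigma2_e, nv)
  X <- rbind(cbind(1, times, 0), cbind(1, times, times))
  Sigma <- matrix(0, 2 * nv, 2 * nv)
  Sigma[1:nv, 1:nv] <- S
  Sigma[(nv + 1):(2 * nv), (nv + 1):(2 * nv)] <- S
  solve(t(X) %*% solve(Sigma) %*% X)[3, 3]
}

# Random valid variance components for property-style loops.
random_vc <- function() {
  s0 <- stats::runif(1, 0.05, 2)
  s1 <- stats::runif(1, 0.001, 0.1)
  rho <- stats::runif(1, -0.95, 0.95)
  variance_components(s0, s1, rho * sqrt(s0 * s1),
                      stats::runif(1, 0.05, 3))
}

# Small two-arm trial fixture shared across fitting tests.
small_trial_fixture <- function(n_total = 8, schedule = 0:2, seed = 3,
                                shape = "early") {
  simulate_trial(shape, treatment_effect("proportional_time", -0.05),
                 variance_components(0.4, 0.02, 0.5 * sqrt(0.4 * 0.02), 0.2),
                 schedule, n_total, seed = seed)
}
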