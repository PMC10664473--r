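test_that("the implied per-person covariance has the random-slopes structure", {
  expect_equal(sigma_person(variance_components(0, 0, 0, 2.5), 0:3),
               diag(2.5, 4))
  S <- sigma_person(variance_components(), 0:5)
  expect_equal(S[1, 1], 0.65)
  expect_equal(S[1, 6], 0.5 + 5 * 0.5 * sqrt(0.005), tolerance = 1e-12)
  withr::with_seed(5, {
    for (i in 1:20) {
      vc <- random_vc()
      expect_no_error(chol(sigma_person(vc, sort(c(0, runif(4, 0.1, 8))))))
    }
  })
})

test_that("the two-person design encodes one control and one treated person", {
  d <- two_person_design(variance_components(), 0:3)
  expect_equal(dim(d$X), c(8, 3))
  expect_equal(d$X[1:4, 3], rep(0, 4))
  expect_equal(d$X[5:8, 3], 0:3)
  expect_equal(d$Sigma[1:4, 1:4], d$Sigma[5:8, 5:8])
  expect_equal(d$Sigma[1:4, 5:8], matrix(0, 4, 4))
})

test_that("the two-person slope variance matches hand and oracle computations", {
  expect_equal(var_gamma_two_person(variance_components(0, 0, 0, 1),
                                    c(0, 1)), 2.0, tolerance = 1e-12)
  v1 <- var_gamma_two_person(variance_components(0, 0, 0, 1), 0:4)
  v2 <- var_gamma_two_person(variance_components(0, 0, 0, 2), 0:4)
  expect_equal(v2, 2 * v1, tolerance = 1e-12)
  withr::with_seed(7, {
    for (i in 1:20) {
      vc <- random_vc()
      sched <- sort(c(0, runif(sample(2:6, 1), 0.2, 9)))
      expect_equal(var_gamma_two_person(vc, sched),
                   stacked_gls_var_oracle(vc, sched), tolerance = 1e-10)
    }
  })
})

test_that("relabelling which person is treated leaves the variance unchanged", {
  vc <- variance_components()
  sched <- 0:5
  d <- two_person_design(vc, sched)
  nv <- length(sched)
  swap <- c((nv + 1):(2 * nv), 1:nv)
  Xs <- d$X[swap, ]
  Xs[, 3] <- Xs[, 3] * 0
  Xs[1:nv, 3] <- sched  # first person treated instead
  V <- solve(t(Xs) %*% solve(d$Sigma) %*% Xs)[3, 3]
  expect_equal(V, var_gamma_two_person(vc, sched), tolerance = 1e-10)
})

test_that("variance scales as the two-person value over N/2", {
  expect_equal(scale_variance(0.3, 2), 0.3)
  expect_equal(scale_variance(2.0, 100), 0.04)
  expect_error(scale_variance(1, 7), "even")

  # empirical SE of the trial slope matches the analytic prediction
  vc <- variance_components()
  n_total <- 100
  pred <- sqrt(scale_variance(var_gamma_two_person(vc, 0:5), n_total))
  gammas <- vapply(1:150, function(s) {
    tr <- simulate_trial("steady", treatment_effect("none"), vc,
                         n_total = n_total, seed = 4000 + s)
    fit_random_slopes(tr, "trial")$gamma
  }, numeric(1))
  emp <- sd(gammas)
  expect_lt(abs(emp - pred), 3 * pred / sqrt(2 * (length(gammas) - 1)))
})

test_that("sample sizes come out even and at the requested power", {
  expect_identical(
    slopes_sample_size(variance_components(0, 0, 0, 1), d = 1,
                       schedule = c(0, 1)), 32L
  )
  vc <- variance_components()
  n <- slopes_sample_size(vc, -0.05, 0:5)
  expect_identical(n %% 2L, 0L)
  expect_gte(analytic_power(vc, -0.05, 0:5, n), 0.8)
  expect_lt(analytic_power(vc, -0.05, 0:5, n - 2L), 0.8)
  # halving the target effect quadruples the bracket before ceiling
  b <- function(d) (qnorm(0.975) + qnorm(0.8))^2 *
    var_gamma_two_person(vc, 0:5) / d^2
  expect_equal(b(-0.025), 4 * b(-0.05))
  expect_error(slopes_sample_size(vc, 0, 0:5), "d != 0")
})

test_that("required size is non-increasing in trial length", {
  curve <- sample_size_curve(variance_components(), d = -0.05,
                             lengths = 2:7)
  expect_true(all(diff(curve$n_total) <= 0))
  one <- sample_size_curve(variance_components(), d = -0.05, lengths = 5)
  expect_identical(one$n_total,
                   slopes_sample_size(variance_components(), -0.05, 0:5))
})

test_that("early- and late-decline fitted components give near-identical curves", {
  fits <- lapply(c("early", "late"), function(s) {
    obs <- simulate_observational(s, n_subjects = 2000,
                                  seed = child_seed(60, "curve", s))
    fit_with_ladder(obs, "observational")$vc_hat
  })
  c_early <- sample_size_curve(fits[[1]], d = -0.05, lengths = 2:7)
  c_late <- sample_size_curve(fits[[2]], d = -0.05, lengths = 2:7)
  rel <- abs(c_early$n_total - c_late$n_total) /
    pmax(c_early$n_total, c_late$n_total)
  expect_lt(max(rel), 0.05)
})

test_that("the pseudo-true slope reproduces proportional effects exactly", {
  sched <- 0:5
  withr::with_seed(12, {
    for (i in 1:5) {
      vc <- random_vc()
      mu_c <- control_mean("late", sched)
      g <- -0.04
      expect_equal(expected_rs_effect(mu_c, mu_c + g * sched, vc, sched),
                   g, tolerance = 1e-10)
      expect_equal(expected_rs_effect(mu_c, mu_c, vc, sched), 0,
                   tolerance = 1e-12)
      shift <- runif(1, -5, 5)
      mu_t <- treated_mean("late",
                           treatment_effect("proportional_control_change",
                                            -0.05), sched)
      expect_equal(
        expected_rs_effect(mu_c + shift, mu_t + shift, vc, sched),
        expected_rs_effect(mu_c, mu_t, vc, sched), tolerance = 1e-10
      )
    }
  })
})

test_that("the pilot workflow ties the pieces together", {
  pilot <- simulate_observational("steady", n_subjects = 500, seed = 9)
  out <- sample_size_from_pilot(pilot, d = -0.05, schedule = 0:3)
  expect_true(out$fit$converged)
  expect_identical(out$n_total,
                   slopes_sample_size(out$fit$vc_hat, -0.05, 0:3))
  expect_equal(out$v_gamma,
               var_gamma_two_person(out$fit$vc_hat, 0:3))
})
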