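test_that("the fast REML criterion matches the full-covariance oracle", {
  trial <- small_trial_fixture(n_total = 8, schedule = 0:2, seed = 3)
  obs <- simulate_observational("late", n_subjects = 8, schedule = 0:2,
                                seed = 4)
  withr::with_seed(99, {
    for (i in 1:5) {
      vc <- random_vc()
      expect_equal(reml_loglik_rs(trial, vc, "trial"),
                   naive_reml_loglik(trial, vc, "trial"),
                   tolerance = 1e-6)
      expect_equal(reml_loglik_rs(obs, vc, "observational"),
                   naive_reml_loglik(obs, vc, "observational"),
                   tolerance = 1e-6)
    }
  })
})

test_that("the restricted likelihood is invariant to shifting all outcomes", {
  trial <- small_trial_fixture()
  vc <- variance_components(0.3, 0.02, 0.01, 0.4)
  shifted <- dplyr::mutate(trial, y = y + 17.3)
  expect_equal(reml_loglik_rs(trial, vc, "trial"),
               reml_loglik_rs(shifted, vc, "trial"), tolerance = 1e-8)
})

test_that("zero random effects reduce REML to the i.i.d. Gaussian criterion", {
  trial <- small_trial_fixture(n_total = 10)
  for (s2e in c(0.2, 1.5)) {
    vc <- variance_components(0, 0, 0, s2e)
    expect_equal(reml_loglik_rs(trial, vc, "trial"),
                 iid_reml_loglik(trial, s2e, "trial"), tolerance = 1e-8)
  }
})

test_that("GLS recovers the fixed effects exactly on noiseless data", {
  # subjects lying exactly on the mean lines: any working covariance must
  # return the generating coefficients
  sched <- 0:4
  noiseless <- tidyr::expand_grid(subject_id = 1:6, time = sched) |>
    dplyr::mutate(arm = as.integer(subject_id > 3),
                  y = 6 + 0.2 * time - 0.07 * arm * time)
  for (vc in list(variance_components(),
                  variance_components(0.9, 0.05, -0.1, 2))) {
    g <- gls_fixed_effects(noiseless, vc, "trial")
    expect_equal(unname(g$beta), c(6, 0.2, -0.07), tolerance = 1e-9)
  }
})

test_that("slope estimate and SE agree with an established mixed-model fitter", {
  skip_if_not_installed("lme4")
  trial <- simulate_trial("steady", treatment_effect("proportional_time",
                                                     -0.05),
                          n_total = 40, seed = 42)
  fit <- fit_random_slopes(trial, "trial")
  ref <- lme4::lmer(
    y ~ time + arm:time + (time | subject_id), data = trial, REML = TRUE,
    control = lme4::lmerControl(optimizer = "bobyqa",
                                check.conv.singular = "ignore")
  )
  expect_equal(fit$gamma, unname(lme4::fixef(ref)[["time:arm"]]),
               tolerance = 1e-4)
  expect_equal(fit$se_gamma,
               sqrt(as.matrix(vcov(ref))["time:arm", "time:arm"]),
               tolerance = 1e-4)
  expect_equal(fit$loglik_reml, as.numeric(stats::logLik(ref)),
               tolerance = 1e-5)
})

test_that("variance components are recovered on a well-behaved cohort", {
  obs <- simulate_observational("steady", n_subjects = 4000, seed = 77)
  fit <- fit_with_ladder(obs, "observational")
  expect_true(fit$converged)
  truth <- unlist(variance_components())
  est <- unlist(fit$vc_hat)
  expect_true(all(abs(est - truth) < 3 * fit$vc_se))
})

test_that("the optimiser ladder records its rung and is deterministic", {
  trial <- simulate_trial("steady", treatment_effect("proportional_time",
                                                     -0.05),
                          n_total = 60, seed = 8)
  f1 <- fit_with_ladder(trial, "trial")
  f2 <- fit_with_ladder(trial, "trial")
  expect_true(f1$converged)
  expect_identical(f1$algorithm_used, "bfgs")
  expect_identical(unlist(f1$vc_hat), unlist(f2$vc_hat))
  expect_identical(f1$gamma, f2$gamma)
})

test_that("heavily non-linear 3-year trials drive the correlation to the boundary", {
  # early-decline 3-year trials: the fitted intercept-slope correlation is
  # expected on the boundary for most datasets
  pc <- treatment_effect("proportional_control_change", -0.05)
  bnd <- vapply(1:6, function(s) {
    tr <- simulate_trial("early", pc, schedule = 0:3, n_total = 600,
                         seed = 100 + s)
    f <- fit_with_ladder(tr, "trial")
    f$converged && f$boundary
  }, logical(1))
  expect_gte(mean(bnd), 0.5)
})

test_that("constrained estimation stays in the valid region and flags the boundary", {
  pc <- treatment_effect("proportional_control_change", -0.05)
  tr <- simulate_trial("early", pc, schedule = 0:3, n_total = 400,
                       seed = 300)
  f <- fit_with_ladder(tr, "trial")
  v <- f$vc_hat
  expect_gte(v$sigma2_u0, 0)
  expect_gte(v$sigma2_u1, 0)
  expect_gt(v$sigma2_e, 0)
  expect_lte(v$sigma_u01^2, v$sigma2_u0 * v$sigma2_u1 * (1 + 1e-8))
  rho <- v$sigma_u01 / sqrt(v$sigma2_u0 * v$sigma2_u1)
  expect_identical(f$boundary, abs(rho) > 0.99)
  if (f$boundary) expect_true(f$converged)
})

test_that("unbalanced or malformed data are rejected with clear errors", {
  trial <- small_trial_fixture()
  expect_error(fit_random_slopes(trial[-1, ], "trial"), "balanced|complete")
  obs <- simulate_observational("steady", n_subjects = 10, seed = 1)
  expect_error(fit_random_slopes(obs, "trial"), "both arms")
  bad <- dplyr::mutate(trial, arm = ifelse(dplyr::row_number() == 1,
                                           1 - arm, arm))
  expect_error(fit_random_slopes(bad, "trial"), "constant within subject")
})
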