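test_that("Monte-Carlo error formulas reproduce their reference values", {
  expect_equal(round(mc_se(0.8, 5000), 1), 0.6)
  expect_equal(round(mc_se(0.05, 5000), 1), 0.3)
  expect_equal(mc_se(0, 1000), 0)
  expect_equal(unname(mc_ci_bounds(0.05, 5000)), c(4.4, 5.6))
  expect_equal(unname(mc_ci_bounds(0.8, 5000)), c(78.8, 81.2))
  expect_equal(unname(mc_ci_bounds(0.8, 1e12)), c(80, 80))
  expect_equal(se_pct_bias(1, 1), 0)
  expect_equal(se_pct_bias(1.1, 1.0), 10, tolerance = 1e-9)
  expect_error(se_pct_bias(1, 0), "positive")
})

test_that("replicates are deterministic given (config, rep_index)", {
  cfg <- scenario_config("steady", "proportional_time", n_reps = 5,
                         base_seed = 123)
  r1 <- run_replicate(cfg, 3)
  r2 <- run_replicate(cfg, 3)
  expect_identical(r1$n_trial, r2$n_trial)
  expect_identical(r1$estimates, r2$estimates)
  expect_identical(r1$obs$vc_hat, r2$obs$vc_hat)
})

test_that("sample sizes are shared across treatment-effect kinds", {
  mk <- function(kind) scenario_config("early", kind, n_reps = 3,
                                       base_seed = 321, models = "rs")
  n_by_kind <- lapply(c("none", "proportional_time",
                        "proportional_control_change"), function(k) {
    vapply(1:3, function(r) run_replicate(mk(k), r)$n_trial, integer(1))
  })
  expect_identical(n_by_kind[[1]], n_by_kind[[2]])
  expect_identical(n_by_kind[[1]], n_by_kind[[3]])
})

test_that("scenario summaries aggregate the replicate estimates correctly", {
  cfg <- scenario_config("steady", "proportional_time", n_reps = 12,
                         base_seed = 99, models = c("rs", "ltfc"))
  s <- run_scenario(cfg, keep_reps = TRUE)
  expect_s3_class(s, "slopes_perf")
  expect_identical(sort(s$model), c("ltfc", "rs"))
  expect_true(all(s$convergence_pct >= 0 & s$convergence_pct <= 100))
  expect_true(all(s$reject_pct >= 0 & s$reject_pct <= 100))

  reps <- attr(s, "reps")
  est <- dplyr::bind_rows(lapply(reps, function(r) r$estimates))
  rs <- dplyr::filter(est, model == "rs")
  row <- dplyr::filter(s, model == "rs")
  expect_equal(row$reject_pct, 100 * mean(rs$reject))
  expect_equal(row$empirical_se, sd(rs$effect_final))
  expect_equal(row$mean_model_se, sqrt(mean(rs$se^2)))
  expect_equal(row$reject_mc_se,
               mc_se(row$reject_pct / 100, row$n_reps_used))
  expect_equal(row$se_pct_bias,
               se_pct_bias(row$mean_model_se, row$empirical_se))
})

test_that("the boundary filter only removes replicates", {
  cfg_all <- scenario_config("early", "none", n_reps = 8, base_seed = 7,
                             models = "rs")
  cfg_flt <- scenario_config("early", "none", n_reps = 8, base_seed = 7,
                             models = "rs",
                             boundary_filter = "exclude_obs_boundary")
  s_all <- run_scenario(cfg_all, keep_reps = TRUE)
  s_flt <- run_scenario(cfg_flt, keep_reps = TRUE)
  reps <- attr(s_all, "reps")
  kept <- !vapply(reps, function(r) isTRUE(r$obs$boundary), logical(1))
  expect_identical(s_flt$n_reps_used, sum(kept))
  # surviving replicates carry identical estimates in both runs
  est_all <- dplyr::bind_rows(lapply(reps[kept],
                                     function(r) r$estimates))
  est_flt <- dplyr::bind_rows(lapply(attr(s_flt, "reps")[kept],
                                     function(r) r$estimates))
  expect_identical(est_all$effect_final, est_flt$effect_final)
})

test_that("the scenario grid applies the factorial rules", {
  g <- build_grid(n_reps = 2)
  expect_identical(nrow(g), 4L * 3L * 2L * 2L)
  cfgs <- g$config
  for (i in seq_len(nrow(g))) {
    cfg <- cfgs[[i]]
    if (cfg$effect_kind %in% c("proportional_time",
                               "proportional_control_change")) {
      expect_equal(cfg$gamma, if (cfg$sigma2_e == 2) -0.1 else -0.05)
    }
    if (cfg$effect_kind == "delayed_decline") {
      expect_identical(cfg$shape, "steady")
      expect_equal(cfg$delay, if (cfg$sigma2_e == 2) 2.5 else 1.25)
    }
    has_fctfc <- "fctfc" %in% cfg$models
    expect_identical(
      has_fctfc,
      cfg$shape == "steady" && cfg$effect_kind == "proportional_time" &&
        max(cfg$trial_schedule) == 5 && cfg$sigma2_e == 0.15
    )
  }
  # delayed decline never appears with a non-steady shape
  nonprop <- dplyr::filter(g, effect_family == "nonproportional")
  expect_true(all(
    (nonprop$shape == "steady") ==
      (nonprop$effect_kind == "delayed_decline")
  ))
})

test_that("scenario configs validate effect-target consistency", {
  expect_error(
    scenario_config("steady", "proportional_time", gamma = -0.05, d = 0.05),
    "same sign"
  )
  cfg <- scenario_config("steady", "none", n_reps = 2)
  expect_equal(cfg$d, -0.05)
  cfg2 <- scenario_config("steady", "none", sigma2_e = 2, n_reps = 2)
  expect_equal(cfg2$d, -0.1)
})

test_that("reports round-trip through CSV", {
  cfg <- scenario_config("late", "proportional_time", n_reps = 6,
                         base_seed = 77, models = c("rs", "ftfc"))
  s <- run_scenario(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  written <- write_report(s, path)
  back <- read_report(path)
  expect_identical(nrow(back), nrow(written))
  expect_identical(names(back), names(written))
  expect_equal(back$reject_pct, written$reject_pct)
  expect_equal(back$mean_effect, written$mean_effect)
  expect_identical(back$shape, written$shape)
})

test_that("YAML scenario configs load with schedule parsing", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "shape: early",
    "effect_kind: proportional_control_change",
    "trial_schedule: \"0,1,2,3\"",
    "n_reps: 4",
    "base_seed: 5"
  ), path)
  cfg <- read_scenario_config(path)
  expect_identical(cfg$shape, "early")
  expect_equal(cfg$trial_schedule, 0:3)
  expect_equal(cfg$gamma, -0.05)
  writeLines(c("shape: early", "bogus_field: 1"), path)
  expect_error(read_scenario_config(path), "Unknown scenario fields")
})

test_that("child seeds are reproducible, distinct and in integer range", {
  s1 <- child_seed(42, "obs", "steady", 0.15, 1)
  expect_identical(s1, child_seed(42, "obs", "steady", 0.15, 1))
  seeds <- vapply(1:200, function(r) child_seed(42, "obs", "steady",
                                                0.15, r), integer(1))
  expect_identical(length(unique(seeds)), 200L)
  expect_true(all(seeds >= 1 & seeds <= .Machine$integer.max))
  expect_false(child_seed(42, "obs", "steady", 0.15, 1) ==
                 child_seed(42, "obs", "steady", 2, 1))
})
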