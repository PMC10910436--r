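test_that("observer draws are seeded and match the population moments", {
  pop <- population_params(1)
  set.seed(5); o1 <- draw_observer(pop, "S1")
  set.seed(5); o2 <- draw_observer(pop, "S1")
  expect_identical(o1, o2)
  # degenerate population: every observer at the means
  pop0 <- pop
  pop0$srf$intercept_sd <- 0; pop0$srf$slope_sd <- 0
  pop0$lca$a_sd <- 0; pop0$lca$b_sd <- 0
  pop0$noise$subject_log_sd <- 0
  pop0$pupil$base_sd <- 0; pop0$pupil$slope_sd <- 0
  pop0$acuity$subject_sd <- 0
  set.seed(1); oa <- draw_observer(pop0)
  set.seed(2); ob <- draw_observer(pop0)
  expect_equal(oa$lca_b, 0.28)
  expect_equal(oa$g_slope, ob$g_slope)
  # sampler spread matches the configured RE SD
  set.seed(99)
  bs <- replicate(1000, draw_observer(pop)$lca_b)
  expect_lt(abs(sd(bs) - 0.45) / 0.45, 0.1)
  expect_true(all(replicate(50, {
    o <- draw_observer(pop); o$near_point_D > o$far_point_D
  })))
})

test_that("steady-state accommodation follows the compensation equation", {
  pop <- population_params(1)
  obs <- mean_observer(pop)
  # green illuminant: the response is the green line, whatever a and b
  green <- list(name = "527.5", peak_nm = 527.5, broadband = FALSE)
  obs2 <- obs; obs2$lca_a <- 3; obs2$lca_b <- -2
  expect_equal(as.numeric(steady_state_accommodation(obs, 2, green, pop)), 1.8)
  expect_equal(as.numeric(steady_state_accommodation(obs2, 2, green, pop)), 1.8)
  # red at the slope-unity distance: full compensation of the LCA defocus
  red <- list(name = "650", peak_nm = 650, broadband = FALSE)
  a <- as.numeric(steady_state_accommodation(obs, 4.5, red, pop))
  expect_equal(a, 4.05 + 1.0 * relative_defocus(650, 527.5), tolerance = 1e-6)
  expect_equal(a, 4.618, tolerance = 1e-3)
  # demands beyond the near point clip to it and flag out-of-range
  obs3 <- obs; obs3$near_point_D <- 5
  a3 <- steady_state_accommodation(obs3, 9, red, pop)
  expect_equal(as.numeric(a3), 5)
  expect_false(attr(a3, "in_range"))
})

test_that("simulated traces hit the configured noise law", {
  pop <- population_params(1)
  obs <- mean_observer(pop)
  blue <- as.list(default_illuminants(1)[1, ])  # 441 nm, offset 0
  # noiseless trace round-trips exactly (covered in preprocess tests too)
  set.seed(3)
  tr <- simulate_trace(obs, 2, blue, 8, quiet_population(1))
  expect_equal(within_trial_rmse(preprocess_trace(tr))$rmse_D, 0,
               tolerance = 1e-12)
  # measured about-trend RMSE near the target at A = 0 for the blue band:
  # generate steady traces at distance giving A ~ 0
  obs0 <- obs; obs0$g_slope <- 0; obs0$g_intercept <- 0
  set.seed(11)
  rmses <- replicate(300, {
    tr <- simulate_trace(obs0, 0, blue, 8, pop)
    tr$valid[is.na(tr$refraction_D)] <- FALSE
    within_trial_rmse(preprocess_trace(tr))$rmse_D
  })
  expect_lt(abs(mean(rmses, na.rm = TRUE) - 0.14) / 0.14, 0.1)
  # same seed gives identical traces
  set.seed(8); t1 <- simulate_trace(obs, 2, blue, 4, pop)
  set.seed(8); t2 <- simulate_trace(obs, 2, blue, 4, pop)
  expect_identical(t1, t2)
})

test_that("experiment simulations produce the protocol trial counts", {
  cfg1 <- experiment_config(1)
  expect_equal(cfg1$n_subjects * length(cfg1$demands_D) *
                 nrow(cfg1$illuminants) * cfg1$repeats / cfg1$n_subjects, 180)
  cfg2 <- experiment_config(2)
  expect_equal(length(cfg2$demands_D) * nrow(cfg2$illuminants) * cfg2$repeats,
               432)
  sim <- simulate_experiment(experiment_config(1, n_subjects = 2, repeats = 1),
                             seed = 4)
  expect_length(sim$traces, 2 * 6 * 6 * 1)
  # experiment 3 demands span the published endpoints through the lens optics
  cfg3 <- experiment_config(3)
  expect_equal(range(round(cfg3$demands_D, 1)), c(-1.0, 6.5))
  expect_length(cfg3$demands_D, 10)
})

test_that("identical seeds reproduce experiments byte-identically", {
  cfg <- experiment_config(2, n_subjects = 2, repeats = 1)
  s1 <- simulate_experiment(cfg, seed = 21)
  s2 <- simulate_experiment(cfg, seed = 21)
  expect_identical(s1$traces, s2$traces)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_trace_csv(s1$traces[[5]], f1)
  write_trace_csv(s2$traces[[5]], f2)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
})

test_that("range clipping produces saturation the gradient rule detects", {
  pop <- population_params(1)
  # near points well inside the tested demands, so the curves genuinely
  # plateau over the last two distances
  pop$range$near_min <- 1.8; pop$range$near_max <- 2.2
  ill <- default_illuminants(1); ill <- ill[!ill$broadband, ]
  cfg <- experiment_config(1, n_subjects = 20, repeats = 2, illuminants = ill)
  sim <- simulate_experiment(cfg, pop, seed = 31)
  summ <- preprocess_experiment(sim$traces)
  curves <- response_curves(summ)
  # nearly all subjects show a detected saturated point at near demands
  per_subj <- tapply(curves$saturated & curves$demand_D >= 2.5,
                     curves$subject, any)
  expect_gte(mean(per_subj), 0.95)
})

test_that("acuity simulation ties thresholds to the generative equation", {
  rows <- simulate_acuity_experiment(
    experiment_config(3, n_subjects = 3, repeats = 1), seed = 17)
  expect_true(all(c("error_D", "median_pupil_mm", "in_linear_range",
                    "threshold_logmar", "true_threshold_logmar")
                  %in% names(rows)))
  expect_true(all(rows$threshold_logmar >= -0.3 &
                    rows$threshold_logmar <= 1.3))
  # same seed reproducibility
  rows2 <- simulate_acuity_experiment(
    experiment_config(3, n_subjects = 3, repeats = 1), seed = 17)
  expect_identical(rows, rows2)
  # zero-error cells: blue-minus-green true contrast equals the default
  pop <- quiet_population(3)
  pop$acuity$subject_sd <- 0
  obs <- mean_observer(pop)
  base <- pop$acuity$base_logmar
  expect_equal(base - (base + pop$acuity$illum_offsets[["528"]]), 0.11)
})
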