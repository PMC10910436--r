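test_that("mixed-model engine reproduces exact fits in the noise-free limit", {
  d <- expand.grid(subject = paste0("S", 1:4), x = seq(0, 3, by = 0.5))
  d$y <- 1 + 2 * d$x
  fit <- fit_lmm(y ~ x, d, random = "(1 | subject)")
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients), c(1, 2), tolerance = 1e-6)
  # CI contains the estimate; AIC identity holds
  expect_true(all(fit$ci95[, "lo"] <= fit$coefficients &
                    fit$coefficients <= fit$ci95[, "hi"]))
  expect_equal(fit$aic, 2 * fit$npar - 2 * fit$loglik, tolerance = 1e-8)
})

test_that("with zero random variance the fit matches the OLS oracle", {
  set.seed(12)
  d <- expand.grid(subject = paste0("S", 1:6), x = seq(-2, 2, by = 0.5))
  d$y <- 0.7 - 1.3 * d$x + rnorm(nrow(d), 0, 0.3)  # no subject effects
  fit <- fit_lmm(y ~ x, d, random = "(1 | subject)")
  ols <- stats::lm(y ~ x, d)
  expect_equal(unname(fit$coefficients), unname(stats::coef(ols)),
               tolerance = 1e-3)
})

test_that("weighted fits with equal weights reproduce the unweighted fit", {
  set.seed(13)
  d <- expand.grid(subject = paste0("S", 1:5), x = 1:6)
  d$y <- 1 + 0.5 * d$x + rnorm(nrow(d), 0, 0.2) +
    rep(rnorm(5, 0, 0.3), times = 6)
  d$w <- 0.8
  f1 <- fit_lmm(y ~ x, d, random = "(1 | subject)")
  f2 <- fit_lmm(y ~ x, d, random = "(1 | subject)", weights = "w")
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-6)
})

test_that("likelihood-ratio test arithmetic and tail probabilities", {
  f <- structure(list(loglik = -100, npar = 10, converged = TRUE),
                 class = "fit_result")
  r <- structure(list(loglik = -110, npar = 5, converged = TRUE),
                 class = "fit_result")
  out <- lrt(f, r)
  expect_equal(out$chi2, 20)
  expect_equal(out$df, 5)
  expect_equal(out$p, stats::pchisq(20, 5, lower.tail = FALSE))
  expect_equal(out$p, 0.001249730, tolerance = 1e-6)
  # identical models: chi2 clamped at 0, p = 1
  same <- lrt(structure(list(loglik = -100, npar = 6), class = "fit_result"), r)
  expect_error(lrt(r, f), "nested")
  r2 <- structure(list(loglik = -99.9, npar = 5), class = "fit_result")
  out2 <- lrt(structure(list(loglik = -100, npar = 6), class = "fit_result"), r2)
  expect_equal(out2$chi2, 0)
  expect_equal(out2$p, 1)
})

test_that("green centering subtracts the cell's green median", {
  df <- data.frame(subject = "S1", distance_D = 2,
                   illuminant = c("441", "527", "661"),
                   median_accommodation_D = c(1.0, 1.3, 1.8),
                   weight = 1, kept = TRUE)
  cen <- center_on_green(df)
  expect_equal(cen$rel_accommodation_D, c(-0.3, 0, 0.5))
  # green-only data: all-zero responses
  g <- df[df$illuminant == "527", ]
  expect_equal(center_on_green(g)$rel_accommodation_D, 0)
  # idempotence
  cen2 <- cen
  cen2$median_accommodation_D <- cen$rel_accommodation_D
  expect_equal(center_on_green(cen2)$rel_accommodation_D,
               cen$rel_accommodation_D)
  # contrasts between non-green illuminants unchanged
  expect_equal(diff(cen$rel_accommodation_D[c(1, 3)]),
               diff(df$median_accommodation_D[c(1, 3)]))
  # cells without green are dropped with a message
  nog <- data.frame(subject = "S1", distance_D = c(2, 3),
                    illuminant = c("441", "441"),
                    median_accommodation_D = c(1, 2), weight = 1, kept = TRUE)
  expect_message(out <- center_on_green(nog), "dropped")
  expect_equal(nrow(out), 0)
})

test_that("LCA-compensation model recovers exact generative coefficients", {
  peaks <- c(441, 460, 527, 588, 661)
  d <- expand.grid(subject = paste0("S", 1:5),
                   distance_D = seq(0.5, 3, by = 0.5), peak_nm = peaks)
  d$illuminant <- as.character(d$peak_nm)
  d$broadband <- FALSE
  d$lca_defocus_D <- relative_defocus(d$peak_nm, 527.5)
  d$rel_accommodation_D <- 0.05 - 0.02 * d$distance_D -
    0.26 * d$lca_defocus_D + 0.28 * d$distance_D * d$lca_defocus_D
  d$weight <- 1
  fit <- fit_lca_compensation(d)
  expect_true(fit$converged)
  co <- fit$coefficients
  expect_equal(unname(co[c("(Intercept)", "distance_D", "lca_defocus_D",
                           "distance_D:lca_defocus_D")]),
               c(0.05, -0.02, -0.26, 0.28), tolerance = 1e-6)
  # green-only data leave the defocus regressor degenerate
  g <- d[d$peak_nm == 527, ]
  expect_error(fit_lca_compensation(g), "degenerate")
})

test_that("slope-unity distance follows from the fitted coefficients", {
  expect_equal(slope_unity_distance(-0.26, 0.28), 4.5)
  expect_equal(slope_unity_distance(0, 1), 1)
  expect_equal(slope_unity_distance(1, 0.37), 0)
  expect_error(slope_unity_distance(0.2, 0), "zero")
})

test_that("variability model back-transforms to percent growth per diopter", {
  # exact generative law: log rmse = log(0.14) + log(1.1495) * A (+ offsets)
  d <- expand.grid(subject = paste0("S", 1:5),
                   mean_accommodation_D = seq(0, 3, by = 0.5),
                   illuminant = c("441", "527", "661"))
  off <- c("441" = 0, "527" = -0.1, "661" = -0.2)
  d$rmse_D <- exp(log(0.14) + log(1.1495) * d$mean_accommodation_D +
                    off[d$illuminant])
  fit <- fit_variability_model(d)
  expect_equal(fit$growth_percent_per_D, 14.95, tolerance = 1e-6)
  expect_equal(fit$intercept_D, 0.14, tolerance = 1e-6)
  # constant RMSEs: zero growth
  d$rmse_D <- 0.2
  expect_equal(fit_variability_model(d)$growth_percent_per_D, 0,
               tolerance = 1e-6)
})

test_that("pupil model recovers a noise-free slope exactly", {
  d <- expand.grid(subject = paste0("S", 1:5),
                   median_accommodation_D = seq(0.5, 3, by = 0.5),
                   illuminant = c("441", "527", "661"))
  off <- c("441" = -0.7, "527" = 0, "661" = 0.6)
  d$median_pupil_mm <- 6 - 0.16 * d$median_accommodation_D + off[d$illuminant]
  fit <- fit_pupil_model(d)
  expect_equal(fit$slope_mm_per_D, -0.16, tolerance = 1e-6)
  # shortest wavelength is the factor baseline
  expect_equal(levels(fit$fit@frame$illuminant)[1], "441")
  # single illuminant: no contrasts, slope still estimated
  one <- d[d$illuminant == "527", ]
  f1 <- fit_pupil_model(one)
  expect_equal(f1$slope_mm_per_D, -0.16, tolerance = 1e-6)
  expect_length(f1$coefficients, 2)
})

test_that("acuity models apply the published exclusion rules", {
  set.seed(21)
  toy <- data.frame(subject = rep(c("A", "B"), 5),
                    illuminant = "459",
                    threshold_logmar = runif(10, 0, 0.5),
                    error_D = rnorm(10),
                    median_pupil_mm = c(3.2, 3.9, 3.5, rep(5, 7)),
                    in_linear_range = TRUE)
  fits <- fit_acuity_models(toy)
  expect_equal(unname(fits$exclusion_counts["pupil_below_4mm"]), 3)
  # noise-free generative contrast (blue baseline) recovered exactly
  d <- expand.grid(subject = paste0("S", 1:5),
                   illuminant = c("459", "528", "610"),
                   error_D = c(-0.6, -0.2, 0.3, 0.8),
                   KEEP.OUT.ATTRS = FALSE)
  off <- c("459" = 0, "528" = -0.11, "610" = -0.08)
  d$threshold_logmar <- 0.04 + off[as.character(d$illuminant)] +
    ifelse(d$error_D < 0, 0.10, 0.12) * abs(d$error_D)
  d$median_pupil_mm <- 5
  d$in_linear_range <- TRUE
  fits <- fit_acuity_models(d)
  co <- fits$linear_range$coefficients
  expect_equal(unname(co[["illuminant528"]]), -0.11, tolerance = 1e-6)
  expect_equal(unname(co[["illuminant610"]]), -0.08, tolerance = 1e-6)
  # estimated marginal means are reported per illuminant
  expect_true(!is.null(fits$emm_linear_range))
  expect_equal(nrow(fits$emm_linear_range), 3)
  # over-accommodation stratum drops saturated rows
  d2 <- d
  d2$error_D <- abs(d2$error_D) + 5.4  # some magnitudes beyond 5.5
  d2$threshold_logmar <- pmin(d2$threshold_logmar + 1.0, 1.4)
  fits2 <- fit_acuity_models(d2)
  expect_gt(unname(fits2$exclusion_counts["overacc_saturated"]), 0)
})

test_that("model comparison: strong interactions win both LRT and AIC", {
  sim <- simulate_experiment(experiment_config(1, repeats = 3), seed = 3)
  summ <- preprocess_experiment(sim$traces)
  f_full <- fit_srf_model(summ, interaction = TRUE)
  f_red <- fit_srf_model(summ, interaction = FALSE)
  out <- lrt(f_full, f_red)
  expect_gt(out$df, 0)
  expect_gt(out$chi2, 2 * out$df)
  # AIC / LRT consistency
  expect_lt(f_full$aic, f_red$aic)
  expect_lt(out$p, 0.05)
})

test_that("a synthetic lagging observer yields negative mean error", {
  pop <- quiet_population(1)
  pop$srf$broadband_slope_multiplier <- 1  # pure 0.9 d green line
  obs <- mean_observer(pop)
  ill <- list(name = "D65", peak_nm = 560, broadband = TRUE)
  d <- seq(0.5, 5, by = 0.5)
  a <- vapply(d, function(x)
    as.numeric(steady_state_accommodation(obs, x, ill, pop)), 0)
  err <- accommodative_error(a, d, ill)
  expect_true(all(err < 0))
  # the lag deepens toward the -0.5 D asymptote at 5 D
  expect_equal(err[d == 5], -0.5, tolerance = 1e-9)
})
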