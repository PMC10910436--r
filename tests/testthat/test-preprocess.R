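test_that("blink masking invalidates the guard window around missing runs", {
  # missing run at samples 101-105 (50 Hz): 3 samples before, 6 after
  pupil <- rep(5, 200)
  pupil[101:105] <- NA
  tr <- mark_blinks(make_trace(rep(2, 200), pupil))
  expect_false(any(tr$valid[98:111]))
  expect_true(all(tr$valid[c(1:97, 112:200)]))

  # missing sample at the first index: pre-window clipped at the start
  pupil <- rep(5, 50)
  pupil[1] <- NA
  tr <- mark_blinks(make_trace(rep(2, 50), pupil))
  expect_false(any(tr$valid[1:7]))
  expect_true(all(tr$valid[8:50]))

  # no missing samples: no change; and masking is idempotent
  clean <- make_trace(rep(2, 100))
  expect_identical(mark_blinks(clean)$valid, clean$valid)
  once <- mark_blinks(make_trace(rep(2, 200), pupil = {
    p <- rep(5, 200); p[30:31] <- NA; p[90] <- NA; p
  }))
  expect_identical(mark_blinks(once)$valid, once$valid)
})

test_that("refraction limit excludes beyond 25 D, strictly and by magnitude", {
  tr <- make_trace(c(26, 25, -30, 2, -25))
  tr <- apply_refraction_limit(tr)
  expect_identical(tr$valid, c(FALSE, TRUE, FALSE, TRUE, TRUE))
})

test_that("onset trimming invalidates the configured initial window", {
  tr <- make_trace(rep(2, 400))
  expect_equal(sum(!trim_onset(tr, 1500)$valid), 75)
  expect_equal(sum(!trim_onset(tr, 2000)$valid), 100)
  expect_identical(trim_onset(tr, 0)$valid, tr$valid)
})

test_that("calibration scales refraction only and inverts exactly", {
  tr <- make_trace(c(2, 1, 3), pupil = c(4, 5, 6))
  expect_identical(apply_calibration(tr, 1), tr)
  g <- apply_calibration(tr, 1.2)
  expect_equal(g$refraction_D, c(2.4, 1.2, 3.6))
  expect_equal(g$pupil_mm, tr$pupil_mm)
  expect_equal(apply_calibration(g, 1 / 1.2)$refraction_D, tr$refraction_D)
  expect_error(apply_calibration(tr, 0), "positive")
})

test_that("trial summaries weight by valid samples in the post-onset window", {
  # 8 s trial, 1.5 s onset: 325 window samples; invalidate 65 -> weight 0.8
  tr <- make_trace(rep(2, 400))
  tr <- trim_onset(tr, 1500)
  tr$valid[76:140] <- FALSE
  sm <- summarize_trial(tr, meta = trial_meta("S1", 1, "527", distance_D = 2))
  expect_equal(sm$weight, 260 / 325)
  expect_equal(sm$n_valid, 260)
  expect_true(sm$kept)

  # 49 valid samples (980 ms) falls below the 1000 ms rule
  tr <- make_trace(rep(2, 49))
  sm <- summarize_trial(tr, meta = trial_meta("S1", 1, "527", distance_D = 2))
  expect_false(sm$kept)

  # medians are order-independent over the valid samples
  vals <- c(2.0, 2.1, 1.9, 2.0, 2.3, 1.7, 2.05, rep(2, 93))
  m1 <- summarize_trial(make_trace(vals),
                        meta = trial_meta("S", 1, "527", 1))
  m2 <- summarize_trial(make_trace(sample(vals)),
                        meta = trial_meta("S", 1, "527", 1))
  expect_equal(m1$median_accommodation_D, stats::median(vals))
  expect_equal(m1$median_accommodation_D, m2$median_accommodation_D)

  # zero valid samples: undefined medians, not kept
  tr <- make_trace(rep(30, 100))  # all beyond the refraction limit
  sm <- summarize_trial(apply_refraction_limit(tr),
                        meta = trial_meta("S", 1, "527", 1))
  expect_false(sm$kept)
  expect_true(is.na(sm$median_accommodation_D))
})

test_that("cleaning operations commute and only clear validity flags", {
  set.seed(101)
  for (i in 1:20) {
    n <- sample(100:300, 1)
    refraction <- rnorm(n, 2, 8)
    pupil <- rep(5, n)
    pupil[sample(n, sample(0:10, 1))] <- NA
    tr <- make_trace(refraction, pupil)
    o1 <- trim_onset(apply_refraction_limit(mark_blinks(tr)), 1000)
    o2 <- mark_blinks(apply_refraction_limit(trim_onset(tr, 1000)))
    o3 <- apply_refraction_limit(trim_onset(mark_blinks(tr), 1000))
    expect_identical(o1$valid, o2$valid)
    expect_identical(o1$valid, o3$valid)
    # flags never resurrect
    expect_true(all(tr$valid | !o1$valid))
    # weight bounded in [0, 1]
    w <- summarize_trial(o1, meta = trial_meta("S", 1, "527", 1))$weight
    expect_gte(w, 0); expect_lte(w, 1)
  }
})

test_that("blink invalidation count is bounded by runs times the window size", {
  set.seed(7)
  for (i in 1:10) {
    pupil <- rep(5, 250)
    miss <- sample(250, sample(1:20, 1))
    pupil[miss] <- NA
    tr <- mark_blinks(make_trace(rep(2, 250), pupil))
    runs <- sum(rle(is.na(pupil))$values)
    expect_lte(sum(!tr$valid), length(miss) + runs * (3 + 6))
  }
})

test_that("the pipeline recovers the true median of a clean trace exactly", {
  pop <- quiet_population(1)
  obs <- mean_observer(pop)
  ill <- as.list(default_illuminants(1)[5, ])  # 661 nm
  set.seed(1)
  tr <- simulate_trace(obs, 2, ill, 8, pop,
                       meta = trial_meta("M", 1, "661", distance_D = 2))
  tr <- preprocess_trace(tr)
  sm <- summarize_trial(tr)
  a_expected <- as.numeric(steady_state_accommodation(obs, 2, ill, pop))
  expect_equal(sm$median_accommodation_D, a_expected, tolerance = 1e-12)
  expect_equal(sm$weight, 1)
  v <- within_trial_rmse(tr)
  expect_equal(v$rmse_D, 0, tolerance = 1e-12)
})
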