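#' Population parameters for the synthetic observer model
#'
#' Generative defaults for drawing synthetic observers and trials. Values with
#' a published anchor: the LCA-compensation coefficients and random-effect SDs
#' (intercept 0 used in place of the n.s. 0.05, RE SD 0.19; distance slope
#' 0.9 with RE SD 0.05; LCA defocus -0.26, RE SD 1.14; distance x LCA defocus
#' 0.28, RE SD 0.45), the variability intercept 0.14 D at the
#' shortest-wavelength illuminant and 14.95% growth per diopter, the pupil
#' slopes (-0.75 / -0.16 / -0.18 mm/D by experiment profile) and illuminant
#' spans (1.70 / 1.40 / 0.45 mm), the acuity coefficients (0.04 logMAR at
#' blue, illuminant contrasts -0.11 / -0.08 / -0.09, in-range error slopes
#' 0.10 / 0.12, out-of-range 0.21 + 0.08/mm and 0.06 + 0.04/mm), and the
#' -0.5 D near lag (green-line slope 0.9). Remaining knobs (LED bandwidths,
#' noise offsets between illuminants, pupil baselines, blink statistics,
#' accommodative ranges) are free parameters chosen as realistic; see the
#' methods vignette.
#'
#' @param experiment Experiment profile (1, 2 or 3); selects the pupil slope
#'   and illuminant-offset set.
#' @return A nested list of class `population_params`.
#' @export
population_params <- function(experiment = 1) {
  stopifnot(experiment %in% 1:3)
  pupil_offsets <- switch(as.character(experiment),
    "1" = c("441" = -0.85, "460" = -0.60, "527" = -0.10, "588" = 0.55,
            "661" = 0.85, "D65" = -0.10),
    "2" = c("441" = -0.70, "460" = -0.50, "527" = -0.05, "588" = 0.70,
            "661" = 0.60, "D65" = -0.05),
    "3" = c("459" = -0.225, "528" = 0, "610" = 0.225, "RGB" = 0))
  pupil_slope <- switch(as.character(experiment),
    "1" = -0.75, "2" = -0.16, "3" = -0.18)
  structure(list(
    experiment = experiment,
    srf = list(intercept_mean = 0, intercept_sd = 0.19,
               slope_mean = 0.9, slope_sd = 0.05,
               lag_asymptote_D = -0.5,
               broadband_slope_multiplier = 1.05),
    lca = list(a_mean = -0.26, a_sd = 1.14,
               b_mean = 0.28, b_sd = 0.45),
    range = list(far_min = 0, far_max = 0.5, near_min = 5, near_max = 9),
    noise = list(rmse0_D = 0.14, growth_per_D = 0.1495,
                 subject_log_sd = 0.2,
                 illum_log_offsets = c(blue = 0, green = -0.15,
                                       long = -0.25, broadband = -0.25)),
    pupil = list(base_mean = 6.3, base_sd = 0.6,
                 slope_per_D = pupil_slope, slope_sd = 0.05,
                 offsets_mm = pupil_offsets, noise_sd_mm = 0.15),
    acuity = list(base_logmar = 0.04, subject_sd = 0.05,
                  illum_offsets = c("459" = 0, "528" = -0.11, "610" = -0.08,
                                    "RGB" = -0.09),
                  slope_neg = 0.10, slope_pos = 0.12,
                  out_pos_slope = 0.21, out_pos_pupil = 0.08,
                  out_neg_slope = 0.06, out_neg_pupil = 0.04,
                  saturation_logmar = 1.2,
                  psycho_slope = 0.08, lapse_rate = 0.01),
    blink = list(rate_hz = 0.25, dur_mean_ms = 150, dur_sd_ms = 50,
                 spike_prob = 0.3),
    dynamics = list(tonic_D = 1.0, latency_s = 0.3, tau_s = 0.25,
                    settle_s = 1.2, noise_cutoff_hz = 2)
  ), class = "population_params")
}

# map an illuminant row to its microfluctuation log offset band
noise_log_offset <- function(pop, peak_nm, broadband) {
  off <- pop$noise$illum_log_offsets
  if (broadband) return(off[["broadband"]])
  if (peak_nm <= 480) off[["blue"]]
  else if (peak_nm <= 560) off[["green"]]
  else off[["long"]]
}

#' Draw one synthetic observer
#'
#' Independent normal draws of every subject-level component (LCA
#' compensation coefficients, green-line intercept and slope, pupil baseline
#' and slope, noise scale, acuity baseline) and uniform draws of the
#' accommodative range. Uses the session RNG, so draws are deterministic
#' under `set.seed()`.
#'
#' @param pop A [population_params()].
#' @param subject_id Subject label.
#' @return A list of class `observer_params`.
#' @export
draw_observer <- function(pop, subject_id = "S1") {
  with(pop, structure(list(
    subject_id = subject_id,
    g_intercept = stats::rnorm(1, srf$intercept_mean, srf$intercept_sd),
    g_slope = stats::rnorm(1, srf$slope_mean, srf$slope_sd),
    lca_a = stats::rnorm(1, lca$a_mean, lca$a_sd),
    lca_b = stats::rnorm(1, lca$b_mean, lca$b_sd),
    far_point_D = stats::runif(1, range$far_min, range$far_max),
    near_point_D = stats::runif(1, range$near_min, range$near_max),
    noise_scale = exp(stats::rnorm(1, 0, noise$subject_log_sd)),
    pupil_base_mm = stats::rnorm(1, pupil$base_mean, pupil$base_sd),
    pupil_slope = stats::rnorm(1, pupil$slope_per_D, pupil$slope_sd),
    acuity_base = stats::rnorm(1, acuity$base_logmar, acuity$subject_sd)
  ), class = "observer_params"))
}

#' Steady-state accommodation of a synthetic observer
#'
#' The observer's green-response line `g(d) = intercept + slope * d` plus the
#' wavelength shift `(a + b * d) * dLCA` (relative defocus of the illuminant
#' peak about 527.5 nm), clipped to the observer's accommodative range.
#' Broadband illuminants have zero LCA shift and a slightly steeper green
#' line. The returned value carries an `in_range` attribute (`FALSE` when the
#' clip was active, i.e. the demand lies outside the accommodative range).
#'
#' @param obs An [draw_observer()] result.
#' @param distance_D Dioptric stimulus distance (effective demand for
#'   trial-lens conditions).
#' @param illum Illuminant row/list with `peak_nm` and `broadband`.
#' @param pop A [population_params()] (for the broadband slope multiplier).
#' @param model A [chromatic_eye_model()].
#' @return Accommodation in diopters with attribute `in_range`.
#' @export
steady_state_accommodation <- function(obs, distance_D, illum,
                                       pop = population_params(),
                                       model = chromatic_eye_model()) {
  broadband <- isTRUE(illum$broadband)
  dl <- if (broadband) 0 else relative_defocus(illum$peak_nm, 527.5, model)
  slope <- obs$g_slope *
    if (broadband) pop$srf$broadband_slope_multiplier else 1
  a_un <- obs$g_intercept + slope * distance_D +
    (obs$lca_a + obs$lca_b * distance_D) * dl
  a <- pmin(pmax(a_un, obs$far_point_D), obs$near_point_D)
  attr(a, "in_range") <- a_un == a
  a
}

#' Simulate one 50 Hz photorefraction trace
#'
#' Builds a refraction trace as an onset transient (300 ms latency, 250 ms
#' exponential approach, settled by 1.2 s) toward the observer's steady-state
#' accommodation, plus low-pass (AR(1), ~2 Hz cutoff) microfluctuation noise
#' whose about-trend RMSE equals
#' `rmse0 * (1 + growth)^A * exp(illuminant offset) * subject scale`,
#' with a pupil channel `base + slope * A + offset(illuminant)` plus slow
#' noise, and blinks inserted as missing bursts (optionally followed by a
#' large refraction spike, as photorefractors produce).
#'
#' @param obs Observer from [draw_observer()].
#' @param distance_D Stimulus distance in diopters.
#' @param illum Illuminant row/list (`name`, `peak_nm`, `broadband`).
#' @param duration_s Trial duration in seconds.
#' @param pop A [population_params()].
#' @param meta Optional [trial_meta()] to attach.
#' @param sample_rate_hz Sampling rate.
#' @param model Chromatic eye model.
#' @return An [acc_trace()].
#' @export
simulate_trace <- function(obs, distance_D, illum, duration_s,
                           pop = population_params(), meta = list(),
                           sample_rate_hz = 50,
                           model = chromatic_eye_model()) {
  fs <- sample_rate_hz
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  dyn <- pop$dynamics
  a_ss <- as.numeric(steady_state_accommodation(obs, distance_D, illum, pop,
                                                model))
  # onset transient, exactly settled at settle_s so trimmed analyses see a
  # constant steady state
  denom <- 1 - exp(-(dyn$settle_s - dyn$latency_s) / dyn$tau_s)
  frac <- (1 - exp(-(t - dyn$latency_s) / dyn$tau_s)) / denom
  frac[t < dyn$latency_s] <- 0
  frac[t >= dyn$settle_s] <- 1
  frac <- pmin(pmax(frac, 0), 1)
  path <- dyn$tonic_D + (a_ss - dyn$tonic_D) * frac

  rmse_target <- pop$noise$rmse0_D * (1 + pop$noise$growth_per_D)^a_ss *
    exp(noise_log_offset(pop, illum$peak_nm, isTRUE(illum$broadband))) *
    obs$noise_scale
  refraction <- path
  if (rmse_target > 0) {
    phi <- exp(-2 * pi * dyn$noise_cutoff_hz / fs)
    eps <- stats::rnorm(n, 0, rmse_target * sqrt(1 - phi^2))
    noise <- stats::filter(eps, phi, method = "recursive",
                           init = stats::rnorm(1, 0, rmse_target))
    refraction <- path + as.numeric(noise)
  }

  pupil_ss <- obs$pupil_base_mm + obs$pupil_slope * a_ss +
    unname(pop$pupil$offsets_mm[illum$name] %||% 0)
  pupil <- rep(pupil_ss, n)
  if (pop$pupil$noise_sd_mm > 0) {
    phi_p <- 0.95
    eps_p <- stats::rnorm(n, 0, pop$pupil$noise_sd_mm * sqrt(1 - phi_p^2))
    pupil <- pupil + as.numeric(stats::filter(
      eps_p, phi_p, method = "recursive",
      init = stats::rnorm(1, 0, pop$pupil$noise_sd_mm)))
  }
  pupil <- pmax(pupil, 1)

  # blinks: missing bursts in both channels, occasionally followed by a
  # refraction spike beyond the plausible range
  bl <- pop$blink
  k <- stats::rpois(1, bl$rate_hz * duration_s)
  if (k > 0) {
    starts <- sort(stats::runif(k, 0, duration_s))
    for (s0 in starts) {
      dur_ms <- max(40, stats::rnorm(1, bl$dur_mean_ms, bl$dur_sd_ms))
      i0 <- max(1L, 1L + floor(s0 * fs))
      i1 <- min(n, i0 + ceiling(dur_ms / 1000 * fs) - 1L)
      pupil[i0:i1] <- NA
      refraction[i0:i1] <- NA
      if (i1 < n && stats::runif(1) < bl$spike_prob) {
        refraction[i1 + 1L] <- sample(c(-1, 1), 1) * stats::runif(1, 26, 40)
      }
    }
  }
  acc_trace(t, refraction, pupil, sample_rate_hz = fs, meta = meta)
}

#' Experiment configuration profiles
#'
#' The three protocol profiles: physical-distance blocks at 0.5-3 D in 0.5 D
#' steps with six LED illuminants (8 s x 5 repeats, or 3 s x 12 repeats with
#' constant angular size), and the trial-lens profile (screen at 1 m viewed
#' through +2 ... -7 D lenses, four screen illuminants, staircase-length
#' trials x 3 repeats).
#'
#' @param experiment 1, 2 or 3.
#' @param n_subjects Number of subjects (defaults 8 / 9 / 10).
#' @param repeats Repeats per condition (defaults 5 / 12 / 3).
#' @param duration_s Trial duration (defaults 8 / 3 / 24 s).
#' @param illuminants Illuminant registry data.frame
#'   (default [default_illuminants()]).
#' @param demands_D Stimulus distances, diopters (experiments 1-2).
#' @param lens_D Trial-lens powers, diopters (experiment 3).
#' @param screen_D,vertex_m Screen distance and lens vertex (experiment 3).
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(experiment, n_subjects = NULL, repeats = NULL,
                              duration_s = NULL, illuminants = NULL,
                              demands_D = seq(0.5, 3, by = 0.5),
                              lens_D = seq(2, -7, by = -1),
                              screen_D = 1, vertex_m = 0.03) {
  stopifnot(experiment %in% 1:3)
  n_subjects <- n_subjects %||% c(8, 9, 10)[experiment]
  repeats <- repeats %||% c(5, 12, 3)[experiment]
  duration_s <- duration_s %||% c(8, 3, 24)[experiment]
  illuminants <- illuminants %||% default_illuminants(experiment)
  if (experiment == 3) {
    demands_D <- effective_demand(screen_D, lens_D, vertex_m)
  } else {
    lens_D <- rep(NA_real_, length(demands_D))
  }
  structure(list(experiment = experiment, n_subjects = n_subjects,
                 repeats = repeats, duration_s = duration_s,
                 illuminants = illuminants, demands_D = demands_D,
                 lens_D = lens_D, screen_D = screen_D, vertex_m = vertex_m),
            class = "experiment_config")
}

#' Simulate a complete experiment
#'
#' Draws `n_subjects` observers and simulates every
#' subject x demand x illuminant x repeat trial as a 50 Hz trace. Trial-lens
#' demands are computed through [effective_demand()]. Fully deterministic
#' given `seed`.
#'
#' @param config An [experiment_config()].
#' @param pop A [population_params()] (defaults to the config's experiment
#'   profile).
#' @param seed Integer seed.
#' @return A list with `traces` (list of [acc_trace()]), `observers`,
#'   `config`, `pop` and `seed`.
#' @export
simulate_experiment <- function(config, pop = NULL, seed = 1) {
  pop <- pop %||% population_params(config$experiment)
  set.seed(seed)
  observers <- lapply(seq_len(config$n_subjects), function(i) {
    draw_observer(pop, sprintf("S%02d", i))
  })
  ill <- config$illuminants
  traces <- vector("list",
                   config$n_subjects * length(config$demands_D) *
                     nrow(ill) * config$repeats)
  idx <- 0L
  for (si in seq_len(config$n_subjects)) {
    obs <- observers[[si]]
    for (di in seq_along(config$demands_D)) {
      for (li in seq_len(nrow(ill))) {
        for (rep_i in seq_len(config$repeats)) {
          idx <- idx + 1L
          meta <- trial_meta(obs$subject_id, config$experiment,
                             ill$name[li],
                             distance_D = config$demands_D[di],
                             lens_D = config$lens_D[di],
                             trial_index = rep_i)
          traces[[idx]] <- simulate_trace(
            obs, config$demands_D[di], as.list(ill[li, ]),
            config$duration_s, pop, meta = meta)
        }
      }
    }
  }
  list(traces = traces, observers = observers, config = config, pop = pop,
       seed = seed)
}

#' Simulate the acuity experiment (staircases over synthetic observers)
#'
#' For every subject x lens x illuminant x repeat cell: simulates the
#' staircase-length photorefraction trace, reduces it to the cell's median
#' accommodation and pupil diameter, computes the accommodative error against
#' the LCA-adjusted demand, derives the cell's true acuity threshold from the
#' generative acuity equation (separate error slopes within and outside the
#' linear range, pupil-dependent outside it, saturating at 1.2 logMAR), and
#' estimates the observed threshold with a seeded best-PEST staircase.
#'
#' @param config An [experiment_config()] (experiment 3 profile).
#' @param pop A [population_params()].
#' @param seed Integer seed.
#' @param n_trials Staircase length (default 24).
#' @return A data.frame of acuity rows: one per staircase with the true and
#'   observed thresholds, accommodative error, pupil, and linear-range flag.
#' @export
simulate_acuity_experiment <- function(config = experiment_config(3),
                                       pop = NULL, seed = 1, n_trials = 24) {
  stopifnot(config$experiment == 3)
  pop <- pop %||% population_params(3)
  set.seed(seed)
  observers <- lapply(seq_len(config$n_subjects), function(i) {
    draw_observer(pop, sprintf("S%02d", i))
  })
  ill <- config$illuminants
  ac <- pop$acuity
  cfg <- chromacc_config()
  grid <- seq(cfg$staircase$grid_min, cfg$staircase$grid_max,
              by = cfg$staircase$grid_step)
  rows <- vector("list",
                 config$n_subjects * length(config$demands_D) * nrow(ill) *
                   config$repeats)
  idx <- 0L
  for (si in seq_len(config$n_subjects)) {
    obs <- observers[[si]]
    for (di in seq_along(config$demands_D)) {
      d <- config$demands_D[di]
      for (li in seq_len(nrow(ill))) {
        illum <- as.list(ill[li, ])
        for (rep_i in seq_len(config$repeats)) {
          idx <- idx + 1L
          meta <- trial_meta(obs$subject_id, 3, illum$name,
                             distance_D = d, lens_D = config$lens_D[di],
                             trial_index = rep_i)
          tr <- simulate_trace(obs, d, illum, config$duration_s, pop,
                               meta = meta)
          tr <- preprocess_trace(tr, onset_ms = 2000)
          sm <- summarize_trial(tr, min_valid_ms = 2000)
          demand <- demand_for_illuminant(d, illum)
          err <- sm$median_accommodation_D - demand
          if (!isTRUE(sm$kept) || is.na(err) || is.na(sm$median_pupil_mm)) {
            next  # unusable recording; slot stays NULL and is dropped
          }
          in_range <- attr(steady_state_accommodation(obs, d, illum, pop),
                           "in_range")
          pupil <- sm$median_pupil_mm
          emag <- abs(err)
          thr <- obs$acuity_base +
            unname(ac$illum_offsets[illum$name] %||% 0) +
            if (in_range) {
              if (err < 0) ac$slope_neg * emag else ac$slope_pos * emag
            } else if (err > 0) {
              (ac$out_pos_slope + ac$out_pos_pupil * (pupil - 4)) * emag
            } else {
              (ac$out_neg_slope + ac$out_neg_pupil * (pupil - 4)) * emag
            }
          thr <- min(thr, ac$saturation_logmar)
          thr <- min(max(thr, grid[1]), grid[length(grid)])
          st <- run_staircase(
            psychometric_observer(thr, slope = ac$psycho_slope,
                                  lapse_rate = ac$lapse_rate),
            n_trials = n_trials, grid = grid,
            template = pest_template(slope = cfg$staircase$template_slope,
                                     lapse_rate = cfg$staircase$template_lapse))
          rows[[idx]] <- data.frame(
            subject = obs$subject_id, experiment = 3L,
            illuminant = illum$name, peak_nm = illum$peak_nm,
            broadband = illum$broadband,
            lens_D = config$lens_D[di], distance_D = d,
            error_D = err, median_pupil_mm = pupil,
            in_linear_range = in_range,
            true_threshold_logmar = thr,
            threshold_logmar = st$threshold_logmar,
            kept = sm$kept,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}
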