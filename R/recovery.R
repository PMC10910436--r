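# Parameter-recovery studies: run the full simulate -> preprocess -> model
# pipeline over several seeded replicates and average the recovered effect.
# These are the package's end-to-end consistency checks; each one's generative
# truth is the corresponding documented default in population_params().

replicate_seeds <- function(n_seeds, seed) {
  set.seed(seed)
  sample.int(.Machine$integer.max %/% 2, n_seeds)
}

#' Recover the distance x LCA-defocus interaction
#'
#' Simulates narrowband physical-distance datasets (17 subjects, six
#' distances, the five narrowband LEDs), runs the preprocessing and
#' green-centering pipeline, fits the LCA-compensation mixed model, and
#' averages the interaction estimate across replicates.
#'
#' @param n_seeds Number of seeded replicates.
#' @param seed Master seed.
#' @param n_subjects,repeats,duration_s Dataset shape per replicate.
#' @return A list: `mean` interaction estimate, per-replicate `estimates`,
#'   their `sd`, the Monte-Carlo 95% CI of the mean, and `n` (rows per fit).
#' @export
recover_lca_interaction <- function(n_seeds = 20, seed = 1, n_subjects = 17,
                                    repeats = 4, duration_s = 8) {
  ill <- default_illuminants(1)
  ill <- ill[!ill$broadband, ]
  seeds <- replicate_seeds(n_seeds, seed)
  est <- numeric(n_seeds)
  n_rows <- NA_integer_
  for (i in seq_along(est)) {
    cfg <- experiment_config(1, n_subjects = n_subjects, repeats = repeats,
                             duration_s = duration_s, illuminants = ill)
    sim <- simulate_experiment(cfg, population_params(1), seed = seeds[i])
    summ <- preprocess_experiment(sim$traces)
    summ <- linear_portion_only(summ)
    centered <- suppressMessages(center_on_green(summ))
    fit <- fit_lca_compensation(centered)
    est[i] <- fit$coefficients[["distance_D:lca_defocus_D"]]
    n_rows <- fit$n_obs
  }
  mc <- stats::sd(est) / sqrt(n_seeds)
  list(mean = mean(est), estimates = est, sd = stats::sd(est),
       ci95 = mean(est) + c(-1, 1) * stats::qt(0.975, n_seeds - 1) * mc,
       n = n_rows)
}

#' Recover the variability growth per diopter
#'
#' Simulates paired physical-distance datasets (long-trial and short-trial
#' profiles, as when the two LED experiments are pooled), computes
#' within-trial RMSE per trial, fits the log-RMSE mixed model, and averages
#' the back-transformed percent growth per diopter.
#'
#' @inheritParams recover_lca_interaction
#' @param repeats_long,repeats_short Repeats for the 8 s and 3 s profiles.
#' @return As [recover_lca_interaction()], for the percent growth.
#' @export
recover_variability_growth <- function(n_seeds = 20, seed = 1,
                                       repeats_long = 5, repeats_short = 12) {
  seeds <- replicate_seeds(n_seeds, seed)
  est <- numeric(n_seeds)
  n_rows <- NA_integer_
  for (i in seq_along(est)) {
    sim1 <- simulate_experiment(
      experiment_config(1, repeats = repeats_long), population_params(1),
      seed = seeds[i])
    sim2 <- simulate_experiment(
      experiment_config(2, repeats = repeats_short), population_params(2),
      seed = seeds[i] + 1L)
    # distinct subject labels so the pooled fit treats them as 17 subjects
    sim2$traces <- lapply(sim2$traces, function(tr) {
      tr$meta$subject_id <- paste0("E2", tr$meta$subject_id)
      tr
    })
    samples <- rbind(variability_samples(sim1$traces),
                     variability_samples(sim2$traces))
    fit <- fit_variability_model(samples)
    est[i] <- fit$growth_percent_per_D
    n_rows <- fit$n_obs
  }
  mc <- stats::sd(est) / sqrt(n_seeds)
  list(mean = mean(est), estimates = est, sd = stats::sd(est),
       ci95 = mean(est) + c(-1, 1) * stats::qt(0.975, n_seeds - 1) * mc,
       n = n_rows)
}

#' Recover the pupil-accommodation slope (constant-angular-size profile)
#'
#' Simulates constant-angular-size datasets, summarizes trials, fits the
#' pupil mixed model, and averages the magnitude of the per-diopter pupil
#' slope.
#'
#' @inheritParams recover_lca_interaction
#' @return As [recover_lca_interaction()], for the slope magnitude in mm/D.
#' @export
recover_pupil_slope <- function(n_seeds = 20, seed = 1, repeats = 12) {
  seeds <- replicate_seeds(n_seeds, seed)
  est <- numeric(n_seeds)
  n_rows <- NA_integer_
  for (i in seq_along(est)) {
    sim <- simulate_experiment(experiment_config(2, repeats = repeats),
                               population_params(2), seed = seeds[i])
    summ <- preprocess_experiment(sim$traces)
    fit <- fit_pupil_model(summ)
    est[i] <- abs(fit$slope_mm_per_D)
    n_rows <- fit$n_obs
  }
  mc <- stats::sd(est) / sqrt(n_seeds)
  list(mean = mean(est), estimates = est, sd = stats::sd(est),
       ci95 = mean(est) + c(-1, 1) * stats::qt(0.975, n_seeds - 1) * mc,
       n = n_rows)
}

#' Recover the blue-vs-green acuity contrast through simulated staircases
#'
#' Simulates the trial-lens acuity experiment (24-trial best-PEST staircases
#' over synthetic observers), fits the linear-range acuity mixed model with
#' the published exclusions, and averages the 459-minus-528 nm contrast at
#' zero accommodative error (the negative of the 528 nm coefficient against
#' the 459 nm baseline).
#'
#' @inheritParams recover_lca_interaction
#' @param n_trials Staircase length.
#' @return As [recover_lca_interaction()], for the contrast in logMAR.
#' @export
recover_acuity_contrast <- function(n_seeds = 20, seed = 1, n_trials = 24) {
  seeds <- replicate_seeds(n_seeds, seed)
  est <- numeric(n_seeds)
  n_rows <- NA_integer_
  for (i in seq_along(est)) {
    rows <- simulate_acuity_experiment(experiment_config(3),
                                       population_params(3),
                                       seed = seeds[i], n_trials = n_trials)
    fits <- fit_acuity_models(rows)
    co <- fits$linear_range$coefficients
    est[i] <- -co[["illuminant528"]]
    n_rows <- fits$linear_range$n_obs
  }
  mc <- stats::sd(est) / sqrt(n_seeds)
  list(mean = mean(est), estimates = est, sd = stats::sd(est),
       ci95 = mean(est) + c(-1, 1) * stats::qt(0.975, n_seeds - 1) * mc,
       n = n_rows)
}
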