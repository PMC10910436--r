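# build a trace from raw channel vectors at 50 Hz
make_trace <- function(refraction, pupil = rep(5, length(refraction)),
                       fs = 50, meta = list()) {
  acc_trace((seq_along(refraction) - 1) / fs, refraction, pupil,
            sample_rate_hz = fs, meta = meta)
}

# population with every noise source silenced: traces reduce exactly to the
# steady-state accommodation and pupil values
quiet_population <- function(experiment = 1) {
  pop <- population_params(experiment)
  pop$noise$rmse0_D <- 0
  pop$noise$subject_log_sd <- 0
  pop$pupil$noise_sd_mm <- 0
  pop$blink$rate_hz <- 0
  pop
}

# deterministic mean observer (all random components at their means)
mean_observer <- function(pop = population_params(1)) {
  list(subject_id = "M",
       g_intercept = pop$srf$intercept_mean,
       g_slope = pop$srf$slope_mean,
       lca_a = pop$lca$a_mean,
       lca_b = pop$lca$b_mean,
       far_point_D = -100,
       near_point_D = 100,
       noise_scale = 1,
       pupil_base_mm = pop$pupil$base_mean,
       pupil_slope = pop$pupil$slope_per_D,
       acuity_base = pop$acuity$base_logmar)
}
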