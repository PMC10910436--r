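#' Photorefraction trace for one trial
#'
#' A sampled refraction / pupil-diameter time series with per-sample validity
#' flags, as produced by a 50 Hz photorefractor. Samples where either channel
#' is missing start out invalid; the cleaning operations
#' ([mark_blinks()], [apply_refraction_limit()], [trim_onset()]) only ever
#' clear validity flags, so their composition order is irrelevant.
#'
#' @param time_s Sample times in seconds, strictly increasing at
#'   `1/sample_rate_hz` spacing.
#' @param refraction_D Refraction per sample in diopters (`NA` for missing).
#' @param pupil_mm Pupil diameter per sample in mm (`NA` for missing).
#' @param valid Optional logical flags; defaults to both channels present.
#' @param sample_rate_hz Sampling rate, Hz.
#' @param meta Named list of trial metadata (see [trial_meta()]).
#' @return An object of class `acc_trace`.
#' @export
acc_trace <- function(time_s, refraction_D, pupil_mm, valid = NULL,
                      sample_rate_hz = 50, meta = list()) {
  n <- length(time_s)
  stopifnot(length(refraction_D) == n, length(pupil_mm) == n)
  if (n > 1) {
    dt <- diff(time_s)
    if (any(dt <= 0)) stop("time must be strictly increasing")
    if (any(abs(dt - 1 / sample_rate_hz) > 1e-6)) {
      stop("time spacing must equal 1/sample_rate_hz")
    }
  }
  present <- !is.na(refraction_D) & !is.na(pupil_mm)
  if (is.null(valid)) valid <- present else valid <- valid & present
  structure(list(time_s = as.numeric(time_s),
                 refraction_D = as.numeric(refraction_D),
                 pupil_mm = as.numeric(pupil_mm),
                 valid = as.logical(valid),
                 sample_rate_hz = sample_rate_hz,
                 onset_s = 0,
                 meta = meta),
            class = "acc_trace")
}

#' @export
print.acc_trace <- function(x, ...) {
  n <- length(x$time_s)
  cat(sprintf("acc_trace: %d samples at %g Hz (%.2f s), %d valid (%.0f%%)\n",
              n, x$sample_rate_hz, if (n) n / x$sample_rate_hz else 0,
              sum(x$valid), if (n) 100 * mean(x$valid) else 0))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=",
                         collapse = ", "), "\n")
  }
  invisible(x)
}

#' Trial metadata
#'
#' @param subject_id Subject label.
#' @param experiment Experiment profile, 1, 2 or 3.
#' @param illuminant Illuminant name.
#' @param distance_D Dioptric stimulus distance (experiments 1-2, or the
#'   effective demand for experiment 3).
#' @param lens_D Trial-lens power in diopters (experiment 3 only).
#' @param trial_index Trial counter within the condition.
#' @return A named list of class `trial_meta`.
#' @export
trial_meta <- function(subject_id, experiment, illuminant,
                       distance_D = NA_real_, lens_D = NA_real_,
                       trial_index = 1L) {
  stopifnot(experiment %in% 1:3)
  if (experiment == 3 && is.na(lens_D) && is.na(distance_D)) {
    stop("experiment 3 trials carry lens_D")
  }
  structure(list(subject_id = subject_id, experiment = experiment,
                 illuminant = as.character(illuminant),
                 distance_D = distance_D, lens_D = lens_D,
                 trial_index = trial_index),
            class = c("trial_meta", "list"))
}

#' Mask blinks and their surroundings
#'
#' Samples where the pupil was not found are blinks; they are invalidated
#' together with a guard window of 60 ms before and 120 ms after each
#' contiguous missing run (windows rounded outward to whole samples).
#' Idempotent: the mask depends only on which samples are missing.
#'
#' @param trace An [acc_trace()].
#' @param before_ms,after_ms Guard window, ms.
#' @return The trace with blink-adjacent samples flagged invalid.
#' @export
mark_blinks <- function(trace, before_ms = 60, after_ms = 120) {
  n <- length(trace$time_s)
  if (n == 0) return(trace)
  missing <- is.na(trace$pupil_mm)
  if (!any(missing)) return(trace)
  nb <- ceiling(before_ms / 1000 * trace$sample_rate_hz)
  na_ <- ceiling(after_ms / 1000 * trace$sample_rate_hz)
  r <- rle(missing)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  bad <- missing
  for (k in which(r$values)) {
    i0 <- max(1L, starts[k] - nb)
    i1 <- min(n, ends[k] + na_)
    bad[i0:i1] <- TRUE
  }
  trace$valid <- trace$valid & !bad
  trace
}

#' Exclude implausible refraction values
#'
#' Photorefractor blink artifacts can produce large refraction spikes; samples
#' whose absolute refraction exceeds `max_abs_D` are invalidated. The
#' comparison is strict (`|x| > max_abs_D`), applied to the absolute value.
#'
#' @param trace An [acc_trace()].
#' @param max_abs_D Limit in diopters.
#' @param signed If `TRUE`, only positive excursions beyond the limit are
#'   excluded.
#' @return The trace with out-of-range samples flagged invalid.
#' @export
apply_refraction_limit <- function(trace, max_abs_D = 25, signed = FALSE) {
  r <- trace$refraction_D
  bad <- if (signed) !is.na(r) & r > max_abs_D else !is.na(r) & abs(r) > max_abs_D
  trace$valid <- trace$valid & !bad
  trace
}

#' Trim the accommodation onset transient
#'
#' Invalidates all samples earlier than `onset_ms` after stimulus onset so the
#' analysis uses the steady-state response only (1500 ms for the
#' physical-distance experiments, 2000 ms for the trial-lens experiment).
#' The trace remembers the onset so trial weights are computed over the
#' post-onset window.
#'
#' @param trace An [acc_trace()].
#' @param onset_ms Length of the excluded onset, ms (>= 0).
#' @return The trace with the onset flagged invalid.
#' @export
trim_onset <- function(trace, onset_ms) {
  stopifnot(onset_ms >= 0)
  onset_s <- onset_ms / 1000
  trace$valid <- trace$valid & !(trace$time_s < onset_s)
  trace$onset_s <- max(trace$onset_s, onset_s)
  trace
}

#' Apply a per-subject calibration gain to refraction
#'
#' The photorefractor's refraction scale is calibrated per subject; the
#' resulting correction is a multiplicative gain (optionally with an additive
#' offset) applied to the refraction channel only.
#'
#' @param trace An [acc_trace()].
#' @param gain Multiplicative gain (> 0).
#' @param offset Additive offset in diopters (default 0).
#' @return The trace with calibrated refraction.
#' @export
apply_calibration <- function(trace, gain, offset = 0) {
  if (!is.numeric(gain) || gain <= 0) stop("calibration gain must be positive")
  trace$refraction_D <- trace$refraction_D * gain + offset
  trace
}

#' Reduce a cleaned trial to summary statistics
#'
#' Computes the median accommodation and pupil diameter over valid samples in
#' the post-onset window, the trial weight (valid samples as a proportion of
#' the samples possible in that window), and whether the trial satisfies the
#' minimum-valid-duration rule (1000 ms for experiments 1-2, 2000 ms for
#' experiment 3).
#'
#' @param trace A cleaned [acc_trace()].
#' @param meta A [trial_meta()] (defaults to the trace's own).
#' @param min_valid_ms Minimum valid duration for the trial to be kept, ms.
#' @return A one-row data.frame with the trial summary.
#' @export
summarize_trial <- function(trace, meta = NULL, min_valid_ms = 1000) {
  if (is.null(meta)) meta <- trace$meta
  window <- trace$time_s >= trace$onset_s
  n_possible <- sum(window)
  ok <- trace$valid & window
  n_valid <- sum(ok)
  weight <- if (n_possible > 0) n_valid / n_possible else 0
  kept <- n_valid > 0 &&
    (n_valid / trace$sample_rate_hz * 1000) >= min_valid_ms
  data.frame(
    subject = meta$subject_id %||% NA_character_,
    experiment = meta$experiment %||% NA_integer_,
    illuminant = meta$illuminant %||% NA_character_,
    distance_D = meta$distance_D %||% NA_real_,
    lens_D = meta$lens_D %||% NA_real_,
    trial = meta$trial_index %||% NA_integer_,
    median_accommodation_D = if (n_valid) stats::median(trace$refraction_D[ok])
                             else NA_real_,
    median_pupil_mm = if (n_valid) stats::median(trace$pupil_mm[ok])
                      else NA_real_,
    weight = weight,
    n_valid = n_valid,
    kept = kept,
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Full cleaning pipeline for one trace
#'
#' Applies blink masking, the refraction limit, onset trimming and the
#' per-subject calibration gain in sequence. The cleaning steps commute; the
#' calibration rescales refraction and is applied last.
#'
#' @param trace An [acc_trace()].
#' @param gain Per-subject calibration gain.
#' @param onset_ms Onset exclusion, ms.
#' @param max_abs_D Refraction limit, D.
#' @param before_ms,after_ms Blink guard windows, ms.
#' @return The cleaned trace.
#' @export
preprocess_trace <- function(trace, gain = 1, onset_ms = 1500,
                             max_abs_D = 25, before_ms = 60, after_ms = 120) {
  trace <- mark_blinks(trace, before_ms, after_ms)
  trace <- apply_refraction_limit(trace, max_abs_D)
  trace <- trim_onset(trace, onset_ms)
  apply_calibration(trace, gain)
}

#' Preprocess every trace of a simulated or loaded experiment
#'
#' Runs [preprocess_trace()] and [summarize_trial()] on each trial, using the
#' experiment-appropriate onset (1500 ms for experiments 1-2, 2000 ms for 3)
#' and minimum-duration (1000 / 2000 ms) rules, and returns the stacked trial
#' summaries. Trials failing the minimum-duration rule are retained in the
#' table with `kept = FALSE`.
#'
#' @param traces A list of [acc_trace()] objects carrying `meta`.
#' @param gains Optional named vector of per-subject calibration gains.
#' @param config A [chromacc_config()] list of processing constants.
#' @return A data.frame of trial summaries.
#' @export
preprocess_experiment <- function(traces, gains = NULL,
                                  config = chromacc_config()) {
  pp <- config$preprocess
  rows <- lapply(traces, function(tr) {
    exp_id <- tr$meta$experiment %||% 1
    onset <- if (exp_id == 3) pp$onset_ms_exp3 else pp$onset_ms_exp12
    min_ms <- if (exp_id == 3) pp$min_valid_ms_exp3 else pp$min_valid_ms_exp12
    g <- 1
    if (!is.null(gains)) {
      sid <- as.character(tr$meta$subject_id)
      if (!is.na(sid) && sid %in% names(gains)) g <- gains[[sid]]
    }
    tr <- preprocess_trace(tr, gain = g, onset_ms = onset,
                           max_abs_D = pp$max_refraction_D,
                           before_ms = pp$blink_before_ms,
                           after_ms = pp$blink_after_ms)
    summarize_trial(tr, min_valid_ms = min_ms)
  })
  do.call(rbind, rows)
}
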