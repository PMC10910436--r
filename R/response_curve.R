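#' Per-point gradients of a stimulus-response curve
#'
#' The gradient of the accommodation response at each demand: central
#' differences for interior points and one-sided differences at the two ends
#' (`method = "forward"` uses forward differences throughout, with a backward
#' difference at the last point).
#'
#' @param demands_D Strictly increasing demands, diopters (>= 2 points).
#' @param responses_D Median accommodation response per demand, diopters.
#' @param method `"central"` (default) or `"forward"`.
#' @return Gradient per point (dimensionless, D per D).
#' @export
point_gradients <- function(demands_D, responses_D,
                            method = c("central", "forward")) {
  method <- match.arg(method)
  n <- length(demands_D)
  if (n < 2 || length(responses_D) != n) {
    stop("need at least two points with matching lengths")
  }
  if (any(diff(demands_D) <= 0)) stop("demands must be strictly increasing")
  g <- numeric(n)
  if (method == "central") {
    g[1] <- (responses_D[2] - responses_D[1]) / (demands_D[2] - demands_D[1])
    g[n] <- (responses_D[n] - responses_D[n - 1]) /
      (demands_D[n] - demands_D[n - 1])
    if (n > 2) {
      i <- 2:(n - 1)
      g[i] <- (responses_D[i + 1] - responses_D[i - 1]) /
        (demands_D[i + 1] - demands_D[i - 1])
    }
  } else {
    i <- 1:(n - 1)
    g[i] <- (responses_D[i + 1] - responses_D[i]) /
      (demands_D[i + 1] - demands_D[i])
    g[n] <- g[n - 1]
  }
  g
}

#' Detect the linear portion of a stimulus-response curve
#'
#' A demand is deemed saturated when its gradient has dropped to half the
#' median gradient or less. The linear portion is then the maximal contiguous
#' unsaturated run containing the point of maximum gradient (when the maximum
#' is tied across runs, the longer run wins); points outside that run are also
#' flagged saturated so the result is always contiguous.
#'
#' @inheritParams point_gradients
#' @param threshold Saturation cutoff as a fraction of the median gradient.
#' @return Logical vector: `TRUE` where the point is outside the linear
#'   portion. If the median gradient is not positive the whole curve is
#'   flagged (attribute `usable` set to `FALSE`).
#' @export
detect_linear_range <- function(demands_D, responses_D, threshold = 0.5,
                                method = c("central", "forward")) {
  g <- point_gradients(demands_D, responses_D, method = match.arg(method))
  n <- length(g)
  med <- stats::median(g)
  if (med <= 0) {
    out <- rep(TRUE, n)
    attr(out, "usable") <- FALSE
    return(out)
  }
  sat <- g <= threshold * med
  # contiguous unsaturated runs
  r <- rle(!sat)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  open_runs <- which(r$values)
  if (!length(open_runs)) {
    out <- rep(TRUE, n)
    attr(out, "usable") <- FALSE
    return(out)
  }
  gmax <- max(g[!sat])
  # runs containing a point achieving the maximum unsaturated gradient
  cand <- open_runs[vapply(open_runs, function(k) {
    any(abs(g[starts[k]:ends[k]] - gmax) < 1e-12)
  }, logical(1))]
  best <- cand[which.max(r$lengths[cand])]
  keep <- starts[best]:ends[best]
  out <- rep(TRUE, n)
  out[keep] <- FALSE
  attr(out, "usable") <- TRUE
  out
}

#' Apply manual saturation overrides
#'
#' Saturation flags were visually inspected in the original workflow and
#' occasionally corrected by hand; this hook applies such corrections from a
#' table of `(subject, illuminant, demand_D, saturated)` rows to a curve's
#' automatic flags. The judgment itself is the analyst's.
#'
#' @param saturated Logical flags from [detect_linear_range()].
#' @param demands_D Demands matching the flags.
#' @param overrides A data.frame with columns `demand_D` and `saturated`
#'   (already filtered to this subject/illuminant).
#' @param tol Demand-matching tolerance, D.
#' @return Corrected logical flags.
#' @export
apply_saturation_overrides <- function(saturated, demands_D, overrides,
                                       tol = 1e-6) {
  if (is.null(overrides) || !nrow(overrides)) return(saturated)
  for (i in seq_len(nrow(overrides))) {
    hit <- abs(demands_D - overrides$demand_D[i]) <= tol
    saturated[hit] <- overrides$saturated[i]
  }
  saturated
}

#' Divide a long trial into equal subsets
#'
#' Staircase-length trials (> 20 s) are divided into `floor(duration/min_s)`
#' equal contiguous subsets of at least `min_s` seconds each (at least one
#' subset); shorter trials pass through whole. The subsets partition the trace
#' exactly.
#'
#' @param trace An [acc_trace()].
#' @param min_s Minimum subset duration, seconds.
#' @return A list of [acc_trace()] objects; each carries a `subset` entry in
#'   its meta.
#' @export
split_subsets <- function(trace, min_s = 5) {
  n <- length(trace$time_s)
  stopifnot(n > 0)
  duration <- n / trace$sample_rate_hz
  k <- max(1L, floor(duration / min_s))
  bounds <- floor(n * (0:k) / k)
  lapply(seq_len(k), function(j) {
    idx <- (bounds[j] + 1L):bounds[j + 1L]
    sub <- trace
    sub$time_s <- trace$time_s[idx]
    sub$refraction_D <- trace$refraction_D[idx]
    sub$pupil_mm <- trace$pupil_mm[idx]
    sub$valid <- trace$valid[idx]
    sub$meta$subset <- j
    sub
  })
}

#' Within-trial response variability (RMSE about a linear trend)
#'
#' Fits an unconstrained straight line to refraction versus time over the
#' valid samples and reports the root-mean-squared error of the residuals
#' (population form, n in the denominator) together with the mean
#' accommodation. The RMSE is invariant to adding any linear time trend, so
#' it measures fluctuation about the trend rather than drift.
#'
#' @param trace An [acc_trace()] (or subset from [split_subsets()]).
#' @param min_valid Minimum number of valid samples (default 3); below it the
#'   trial is marked excluded (`NA` RMSE).
#' @return A one-row data.frame with `mean_accommodation_D`, `rmse_D`,
#'   `n_valid` and the trial metadata.
#' @export
within_trial_rmse <- function(trace, min_valid = 3) {
  ok <- trace$valid & trace$time_s >= trace$onset_s
  t <- trace$time_s[ok]
  y <- trace$refraction_D[ok]
  meta <- trace$meta
  base <- data.frame(
    subject = meta$subject_id %||% NA_character_,
    experiment = meta$experiment %||% NA_integer_,
    illuminant = meta$illuminant %||% NA_character_,
    subset = meta$subset %||% 1L,
    stringsAsFactors = FALSE
  )
  if (length(y) < min_valid) {
    return(cbind(base, mean_accommodation_D = NA_real_, rmse_D = NA_real_,
                 n_valid = length(y)))
  }
  tc <- t - mean(t)
  slope <- sum(tc * y) / sum(tc^2)
  resid <- y - mean(y) - slope * tc
  cbind(base,
        mean_accommodation_D = mean(y),
        rmse_D = sqrt(mean(resid^2)),
        n_valid = length(y))
}

#' Variability samples for a whole experiment
#'
#' Cleans each trace, divides trial-lens-experiment trials into >= 5 s
#' subsets, and computes [within_trial_rmse()] per trial or subset.
#'
#' @param traces List of [acc_trace()] objects with metadata.
#' @param config A [chromacc_config()].
#' @return A data.frame of variability samples.
#' @export
variability_samples <- function(traces, config = chromacc_config()) {
  pp <- config$preprocess
  rows <- lapply(traces, function(tr) {
    exp_id <- tr$meta$experiment %||% 1
    onset <- if (exp_id == 3) pp$onset_ms_exp3 else pp$onset_ms_exp12
    tr <- preprocess_trace(tr, onset_ms = onset,
                           max_abs_D = pp$max_refraction_D,
                           before_ms = pp$blink_before_ms,
                           after_ms = pp$blink_after_ms)
    if (exp_id == 3) {
      subs <- split_subsets(tr, min_s = config$response_curve$subset_min_s)
      do.call(rbind, lapply(subs, within_trial_rmse))
    } else {
      within_trial_rmse(tr)
    }
  })
  do.call(rbind, rows)
}
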