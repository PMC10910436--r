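#' Default run configuration
#'
#' All constants implementing the published processing rules, grouped by
#' pipeline stage, with their standard defaults: blink guard windows (60 ms
#' before, 120 ms after), the 25 D refraction limit, onset exclusions
#' (1500 ms / 2000 ms), minimum valid durations (1000 ms / 2000 ms), the 50%
#' gradient saturation rule, the 5 s subset rule, and the acuity-model
#' exclusion rules (4 mm pupil, 5.5 D error, 1.2 logMAR).
#'
#' @return A nested named list.
#' @export
chromacc_config <- function() {
  list(
    preprocess = list(
      blink_before_ms = 60,
      blink_after_ms = 120,
      max_refraction_D = 25,
      refraction_limit_signed = FALSE,
      onset_ms_exp12 = 1500,
      onset_ms_exp3 = 2000,
      min_valid_ms_exp12 = 1000,
      min_valid_ms_exp3 = 2000,
      calibration_offset_D = 0
    ),
    response_curve = list(
      saturation_threshold = 0.5,
      gradient_method = "central",
      subset_min_s = 5,
      rmse_denominator = "n"
    ),
    optics = list(
      p = 1.7312, q = 0.63346, c = 0.21410,
      reference_nm = 580,
      center_nm = 527.5,
      vertex_m = 0.03,
      broadband_defocus_D = 0,
      Km_lm_per_W = 683
    ),
    inference = list(
      ci_level = 0.95,
      pupil_exclusion_mm = 4,
      overacc_error_limit_D = 5.5,
      overacc_va_limit_logmar = 1.2,
      pupil_center_mm = 4
    ),
    staircase = list(
      n_trials = 24,
      grid_min = -0.3, grid_max = 1.3, grid_step = 0.02,
      template_slope = 0.08,
      template_lapse = 0.01,
      guess_rate = 0.25,
      estimate = "mode"
    )
  )
}

merge_config <- function(defaults, override, path = "") {
  for (key in names(override)) {
    here <- if (nzchar(path)) paste0(path, "$", key) else key
    if (!key %in% names(defaults)) {
      stop("unknown configuration key: ", here)
    }
    if (is.list(defaults[[key]]) && !is.null(override[[key]])) {
      if (!is.list(override[[key]])) {
        stop("configuration key ", here, " must be a section")
      }
      defaults[[key]] <- merge_config(defaults[[key]], override[[key]], here)
    } else {
      defaults[[key]] <- override[[key]]
    }
  }
  defaults
}

#' Load a run configuration from YAML or JSON
#'
#' Reads a (possibly partial) configuration file, validates every key against
#' [chromacc_config()] (unknown keys are an error naming the key), and fills
#' unspecified values with the defaults. An empty file yields the full
#' defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A complete configuration list.
#' @export
load_config <- function(path) {
  stopifnot(file.exists(path))
  override <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(override)) return(chromacc_config())
  merge_config(chromacc_config(), override)
}

#' Read and write trace CSVs
#'
#' One trial per file with columns `t_s,refraction_D,pupil_mm`; missing
#' samples are empty cells and survive a write/read round trip. Metadata
#' columns (`subject,experiment,illuminant,distance_D,lens_D,trial`) are
#' written alongside when present so a directory of files is self-describing.
#'
#' @param trace An [acc_trace()].
#' @param path File path.
#' @return `read_trace_csv` returns an [acc_trace()]; `write_trace_csv`
#'   returns `path` invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  df <- data.frame(t_s = trace$time_s,
                   refraction_D = trace$refraction_D,
                   pupil_mm = trace$pupil_mm)
  m <- trace$meta
  if (length(m)) {
    df$subject <- m$subject_id %||% NA
    df$experiment <- m$experiment %||% NA
    df$illuminant <- m$illuminant %||% NA
    df$distance_D <- m$distance_D %||% NA
    df$lens_D <- m$lens_D %||% NA
    df$trial <- m$trial_index %||% NA
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trace_csv
#' @param sample_rate_hz Sampling rate of the stored trace.
#' @export
read_trace_csv <- function(path, sample_rate_hz = 50) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t_s", "refraction_D", "pupil_mm")
  if (!all(need %in% names(df))) {
    stop("trace CSV must have columns t_s, refraction_D, pupil_mm: ", path)
  }
  meta <- list()
  if ("subject" %in% names(df)) {
    meta <- list(subject_id = df$subject[1],
                 experiment = df$experiment[1],
                 illuminant = as.character(df$illuminant[1]),
                 distance_D = df$distance_D[1],
                 lens_D = df$lens_D[1],
                 trial_index = df$trial[1])
  }
  acc_trace(df$t_s, df$refraction_D, df$pupil_mm,
            sample_rate_hz = sample_rate_hz, meta = meta)
}

#' Read an illuminant registry from YAML
#'
#' A registry is a YAML list of `{name, peak_nm, fwhm_nm, luminance_cdm2,
#' broadband}` entries; the packaged default
#' (`system.file("extdata", "illuminants.yaml", package = "chromacc")`)
#' holds both LED sets.
#'
#' @param path YAML file path.
#' @return A data.frame in the [default_illuminants()] layout.
#' @export
read_illuminants <- function(path) {
  raw <- yaml::read_yaml(path)
  rows <- lapply(raw, function(x) {
    ill <- illuminant(x$name, x$peak_nm, x$fwhm_nm, x$luminance_cdm2,
                      isTRUE(x$broadband))
    data.frame(name = ill$name, peak_nm = ill$peak_nm, fwhm_nm = ill$fwhm_nm,
               luminance_cdm2 = ill$luminance_cdm2, broadband = ill$broadband,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read manual saturation overrides from YAML
#'
#' Overrides are a YAML list of `{subject, illuminant, demand_D, saturated}`
#' entries recording an analyst's corrections to the automatic saturation
#' flags; pass the relevant subset to [apply_saturation_overrides()].
#'
#' @param path YAML file path.
#' @return A data.frame with one row per override.
#' @export
read_saturation_overrides <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(rbind, lapply(raw, function(x) {
    data.frame(subject = as.character(x$subject),
               illuminant = as.character(x$illuminant),
               demand_D = as.numeric(x$demand_D),
               saturated = isTRUE(x$saturated),
               stringsAsFactors = FALSE)
  }))
}

#' Read and write trial-summary tables
#'
#' Plain CSV round trip for the tables produced by
#' [preprocess_experiment()], [variability_samples()] and
#' [simulate_acuity_experiment()].
#'
#' @param rows A data.frame.
#' @param path File path.
#' @export
write_summaries <- function(rows, path) {
  utils::write.csv(rows, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_summaries
#' @export
read_summaries <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
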