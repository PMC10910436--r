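#' Fit a linear mixed model with a random-structure fallback ladder
#'
#' Maximum-likelihood (not REML) fit via lme4, trying the supplied
#' random-effect structures in order from the maximal one downward and keeping
#' the first fit with no convergence failure (the published analyses use "the
#' maximal random-effects structure without convergence issues"). Singular
#' fits — variance components estimated at zero — are tolerated; optimizer
#' convergence failures trigger the next ladder rung. Wald 95% confidence
#' intervals are reported for the fixed effects.
#'
#' @param fixed Fixed-effects formula, e.g. `y ~ x * g`.
#' @param data A data.frame.
#' @param random Character vector of random-effect terms in decreasing
#'   complexity, e.g. `c("(1 + x | subject)", "(1 | subject)")`.
#' @param weights Optional column name (string) of observation weights.
#' @param ci_level Confidence level for the Wald intervals.
#' @return An object of class `fit_result`: `coefficients`, `ci95`, `re_sd`,
#'   `loglik`, `aic`, `npar`, `n_obs`, `converged`, `random_structure`,
#'   `sigma`, and the underlying `fit`.
#' @export
fit_lmm <- function(fixed, data, random, weights = NULL, ci_level = 0.95) {
  stopifnot(inherits(fixed, "formula"), length(random) >= 1)
  data <- as.data.frame(data)
  env <- new.env(parent = parent.frame())
  env$.chromacc_data <- data
  if (!is.null(weights)) {
    stopifnot(is.character(weights), weights %in% names(data))
    env$.chromacc_w <- data[[weights]]
  }
  attempt <- NULL
  used <- NA_character_
  for (re in random) {
    f <- stats::as.formula(paste(deparse(fixed), "+", re))
    environment(f) <- env
    warns <- character()
    m <- tryCatch(
      withCallingHandlers(
        if (is.null(weights)) {
          eval(substitute(lme4::lmer(FF, data = .chromacc_data, REML = FALSE),
                          list(FF = f)), env)
        } else {
          eval(substitute(lme4::lmer(FF, data = .chromacc_data,
                                     weights = .chromacc_w, REML = FALSE),
                          list(FF = f)), env)
        },
        warning = function(w) {
          warns <<- c(warns, conditionMessage(w))
          invokeRestart("muffleWarning")
        }),
      error = function(e) e)
    if (inherits(m, "error")) next
    failed <- any(grepl("failed to converge|convergence code|unable to evaluate",
                        warns, ignore.case = TRUE))
    attempt <- m
    used <- re
    if (!failed) break
  }
  if (is.null(attempt)) {
    return(structure(list(converged = FALSE, random_structure = NA_character_,
                          coefficients = NULL, fit = NULL),
                     class = "fit_result"))
  }
  m <- attempt
  fe <- lme4::fixef(m)
  se <- sqrt(diag(as.matrix(stats::vcov(m))))
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  ci <- cbind(lo = fe - z * se, hi = fe + z * se)
  ll <- stats::logLik(m)
  vc <- lme4::VarCorr(m)
  re_sd <- unlist(lapply(names(vc), function(g) {
    sds <- attr(vc[[g]], "stddev")
    stats::setNames(sds, paste(g, names(sds), sep = "."))
  }))
  structure(list(
    coefficients = fe,
    se = se,
    ci95 = ci,
    re_sd = re_sd,
    sigma = stats::sigma(m),
    loglik = as.numeric(ll),
    npar = attr(ll, "df"),
    aic = stats::AIC(m),
    n_obs = stats::nobs(m),
    converged = TRUE,
    singular = lme4::isSingular(m),
    random_structure = used,
    fit = m
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("fit_result: did not converge at any ladder rung\n")
    return(invisible(x))
  }
  cat("Linear mixed model (ML), random structure:", x$random_structure, "\n")
  tab <- data.frame(estimate = round(x$coefficients, 4),
                    ci_lo = round(x$ci95[, "lo"], 4),
                    ci_hi = round(x$ci95[, "hi"], 4))
  print(tab)
  cat(sprintf("logLik %.2f | AIC %.2f | n = %d%s\n", x$loglik, x$aic,
              x$n_obs, if (isTRUE(x$singular)) " | singular RE fit" else ""))
  if (length(x$re_sd)) {
    cat("RE SDs:", paste(sprintf("%s=%.3f", names(x$re_sd), x$re_sd),
                         collapse = ", "), "\n")
  }
  invisible(x)
}

#' Likelihood-ratio test between nested ML fits
#'
#' @param full,reduced [fit_lmm()] results, reduced nested in full.
#' @return A list with `chi2` (clamped at zero), `df` and `p`.
#' @export
lrt <- function(full, reduced) {
  stopifnot(inherits(full, "fit_result"), inherits(reduced, "fit_result"))
  df <- full$npar - reduced$npar
  if (df <= 0) stop("`reduced` must be nested in (have fewer parameters than) `full`")
  chi2 <- max(0, 2 * (full$loglik - reduced$loglik))
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

# attach peak_nm / broadband columns by illuminant name using the default
# registries (numeric names parse as their peak; D65/RGB are broadband)
resolve_illuminants <- function(df) {
  if (!is.null(df$peak_nm) && !is.null(df$broadband)) return(df)
  reg <- rbind(default_illuminants(1), default_illuminants(3))
  i <- match(as.character(df$illuminant), reg$name)
  if (anyNA(i)) {
    miss <- unique(df$illuminant[is.na(i)])
    num <- suppressWarnings(as.numeric(miss))
    if (anyNA(num)) stop("unknown illuminant(s): ",
                         paste(miss[is.na(num)], collapse = ", "))
  }
  df$peak_nm <- ifelse(is.na(i),
                       suppressWarnings(as.numeric(as.character(df$illuminant))),
                       reg$peak_nm[i])
  df$broadband <- ifelse(is.na(i), FALSE, reg$broadband[i])
  df
}

# factor with the shortest-wavelength narrowband illuminant as baseline
illuminant_factor <- function(illuminant, peak_nm, broadband) {
  key <- ifelse(broadband, Inf, peak_nm)
  lev <- unique(as.character(illuminant)[order(key)])
  factor(as.character(illuminant), levels = lev)
}

#' Center accommodation responses on the green illuminant
#'
#' For each subject x distance cell, subtracts the cell's median response to
#' the green illuminant (527/528 nm) from every trial's response, so the
#' centered value is the relative accommodation between wavelengths; attaches
#' the LCA-defocus regressor (relative defocus of each illuminant's peak
#' about 527.5 nm). Cells without a green trial are dropped (with a message).
#' Centering is idempotent, and contrasts between non-green illuminants
#' within a cell are unchanged.
#'
#' @param summaries Trial-summary data.frame (from
#'   [preprocess_experiment()]); needs `subject`, `distance_D`, `illuminant`,
#'   `median_accommodation_D` (and optionally `kept`, `peak_nm`,
#'   `broadband`).
#' @param green_nm Wavelength window treated as green, nm.
#' @param center_nm Centering wavelength for the defocus regressor.
#' @param model A [chromatic_eye_model()].
#' @return The kept rows with `rel_accommodation_D` and `lca_defocus_D`
#'   columns added.
#' @export
center_on_green <- function(summaries, green_nm = c(525, 530),
                            center_nm = 527.5,
                            model = chromatic_eye_model()) {
  df <- resolve_illuminants(as.data.frame(summaries))
  if (!is.null(df$kept)) df <- df[df$kept %in% c(TRUE, NA), ]
  df <- df[!is.na(df$median_accommodation_D), ]
  is_green <- !df$broadband & df$peak_nm >= green_nm[1] &
    df$peak_nm <= green_nm[2]
  cell <- interaction(df$subject, df$distance_D, drop = TRUE)
  green_med <- tapply(df$median_accommodation_D[is_green], cell[is_green],
                      stats::median)
  med <- green_med[as.character(cell)]
  dropped <- sum(is.na(med))
  if (dropped > 0) {
    message(dropped, " row(s) dropped: no green response in their subject x distance cell")
  }
  df <- df[!is.na(med), ]
  df$rel_accommodation_D <- as.numeric(df$median_accommodation_D -
                                         med[!is.na(med)])
  df$lca_defocus_D <- ifelse(df$broadband, NA_real_,
                             relative_defocus(df$peak_nm, center_nm, model))
  df
}

#' LCA-compensation mixed model
#'
#' Relative (green-centered) accommodation as a function of distance, the LCA
#' defocus of the illuminant's peak wavelength, and their interaction, with
#' subject random intercept and slopes. A positive distance x defocus
#' interaction means observers compensate for LCA more completely at nearer
#' distances; the defocus slope reaches 1 (full compensation) at
#' [slope_unity_distance()].
#'
#' @param centered Output of [center_on_green()] (narrowband rows are used).
#' @param weights Use the trial `weight` column when present.
#' @param ci_level Confidence level.
#' @return A [fit_lmm()] result.
#' @export
fit_lca_compensation <- function(centered, weights = TRUE, ci_level = 0.95) {
  df <- centered[!centered$broadband & !is.na(centered$lca_defocus_D), ]
  if (length(unique(round(df$lca_defocus_D, 6))) < 2) {
    stop("LCA defocus regressor is degenerate (green-only data?)")
  }
  wcol <- if (weights && "weight" %in% names(df)) "weight" else NULL
  fit_lmm(rel_accommodation_D ~ distance_D * lca_defocus_D, df,
          random = c("(1 + distance_D * lca_defocus_D | subject)",
                     "(1 + distance_D + lca_defocus_D | subject)",
                     "(1 + lca_defocus_D | subject)",
                     "(1 | subject)"),
          weights = wcol, ci_level = ci_level)
}

#' Distance at which LCA compensation reaches unity
#'
#' With defocus slope `a` and distance x defocus interaction `b`, the
#' compensation slope `a + b d` equals 1 at `d = (1 - a) / b`.
#'
#' @param a Defocus coefficient.
#' @param b Interaction coefficient (non-zero).
#' @return Distance in diopters.
#' @export
slope_unity_distance <- function(a, b) {
  if (b == 0) stop("interaction coefficient is zero: slope never reaches 1")
  (1 - a) / b
}

#' Accommodative error (response minus demand)
#'
#' Negative errors are lags (focus farther than the stimulus), positive
#' errors leads.
#'
#' @param response_D Accommodation response, D.
#' @param distance_D Dioptric stimulus distance.
#' @param illum Illuminant (see [demand_for_illuminant()]).
#' @param model A [chromatic_eye_model()].
#' @return Error in diopters.
#' @export
accommodative_error <- function(response_D, distance_D, illum,
                                model = chromatic_eye_model()) {
  response_D - demand_for_illuminant(distance_D, illum, model)
}

#' Variability mixed model (log-RMSE growth with accommodation)
#'
#' Log-transformed within-trial RMSEs modelled with mean accommodation as a
#' continuous predictor and illuminant as a categorical one (baseline: the
#' shortest-wavelength illuminant). The accommodation coefficient
#' back-transforms to a percent growth in variability per diopter,
#' `100 (exp(beta) - 1)`; the intercept back-transforms to the baseline RMSE
#' in diopters at 0 D.
#'
#' @param samples Data.frame from [variability_samples()] (needs `subject`,
#'   `illuminant`, `mean_accommodation_D`, `rmse_D`).
#' @param ci_level Confidence level.
#' @return A [fit_lmm()] result with extra elements `intercept_D` and
#'   `growth_percent_per_D`.
#' @export
fit_variability_model <- function(samples, ci_level = 0.95) {
  df <- resolve_illuminants(as.data.frame(samples))
  df <- df[is.finite(df$rmse_D) & df$rmse_D > 0, ]
  df$log_rmse <- log(df$rmse_D)
  df$illuminant <- illuminant_factor(df$illuminant, df$peak_nm, df$broadband)
  fixed <- if (nlevels(df$illuminant) > 1) {
    log_rmse ~ mean_accommodation_D + illuminant
  } else {
    log_rmse ~ mean_accommodation_D
  }
  res <- fit_lmm(fixed, df,
                 random = c("(1 + mean_accommodation_D | subject)",
                            "(1 | subject)"),
                 ci_level = ci_level)
  if (isTRUE(res$converged)) {
    beta <- res$coefficients[["mean_accommodation_D"]]
    res$intercept_D <- exp(res$coefficients[["(Intercept)"]])
    res$growth_percent_per_D <- 100 * (exp(beta) - 1)
  }
  res
}

#' Pupil-size mixed model
#'
#' Median pupil diameter as a function of accommodation (continuous) and
#' illuminant (categorical), with subject random intercept and accommodation
#' slope. Reports the per-diopter pupil slope and the illuminant contrasts
#' against the shortest-wavelength baseline.
#'
#' @param summaries Trial summaries with `median_pupil_mm`,
#'   `median_accommodation_D`, `illuminant`, `subject`.
#' @param ci_level Confidence level.
#' @return A [fit_lmm()] result with extra element `slope_mm_per_D`.
#' @export
fit_pupil_model <- function(summaries, ci_level = 0.95) {
  df <- resolve_illuminants(as.data.frame(summaries))
  if (!is.null(df$kept)) df <- df[df$kept %in% TRUE, ]
  df <- df[!is.na(df$median_pupil_mm) & !is.na(df$median_accommodation_D), ]
  df$illuminant <- illuminant_factor(df$illuminant, df$peak_nm, df$broadband)
  fixed <- if (nlevels(df$illuminant) > 1) {
    median_pupil_mm ~ median_accommodation_D + illuminant
  } else {
    median_pupil_mm ~ median_accommodation_D
  }
  res <- fit_lmm(fixed, df,
                 random = c("(1 + median_accommodation_D | subject)",
                            "(1 | subject)"),
                 ci_level = ci_level)
  if (isTRUE(res$converged)) {
    res$slope_mm_per_D <- res$coefficients[["median_accommodation_D"]]
  }
  res
}

#' Acuity mixed models with the published exclusion rules
#'
#' Fits three models of visual-acuity thresholds after applying the printed
#' exclusions: rows with median pupil below 4 mm are removed from all
#' analyses; the linear-range model uses in-range rows with predictors error
#' magnitude x error sign plus illuminant; the over- and under-accommodation
#' models use the out-of-range-inclusive positive- and negative-error strata
#' with predictors error magnitude x pupil (centered at 4 mm) plus
#' illuminant, the positive stratum additionally dropping saturated rows
#' (error magnitude > 5.5 D or acuity > 1.2 logMAR). Estimated marginal means
#' per illuminant are reported for the linear-range model.
#'
#' @param rows Acuity rows (see [simulate_acuity_experiment()]): `subject`,
#'   `illuminant`, `threshold_logmar`, `error_D`, `median_pupil_mm`,
#'   `in_linear_range`.
#' @param config A [chromacc_config()] (exclusion constants).
#' @param ci_level Confidence level.
#' @return A list with `linear_range`, `overacc`, `underacc` fits (each a
#'   [fit_lmm()] result or `NULL` if the stratum is empty), `emm_linear_range`
#'   (estimated marginal means), and `exclusion_counts`.
#' @export
fit_acuity_models <- function(rows, config = chromacc_config(),
                              ci_level = 0.95) {
  inf <- config$inference
  df <- resolve_illuminants(as.data.frame(rows))
  df <- df[!is.na(df$threshold_logmar) & !is.na(df$error_D) &
             !is.na(df$median_pupil_mm), ]
  n0 <- nrow(df)
  df <- df[df$median_pupil_mm >= inf$pupil_exclusion_mm, ]
  n_pupil_dropped <- n0 - nrow(df)
  df$illuminant <- illuminant_factor(df$illuminant, df$peak_nm, df$broadband)
  df$err_mag <- abs(df$error_D)
  df$err_sign <- factor(ifelse(df$error_D < 0, "neg", "pos"),
                        levels = c("neg", "pos"))
  df$pupil_c <- df$median_pupil_mm - inf$pupil_center_mm

  fit_or_null <- function(sub, fixed, note) {
    if (!nrow(sub)) {
      message("acuity stratum skipped (no rows): ", note)
      return(NULL)
    }
    fit_lmm(fixed, sub,
            random = c("(1 + err_mag | subject)", "(1 | subject)"),
            ci_level = ci_level)
  }

  lin <- df[df$in_linear_range %in% TRUE, ]
  fit_lin <- fit_or_null(lin, threshold_logmar ~ err_mag * err_sign + illuminant,
                         "linear range")

  over <- df[df$error_D > 0, ]
  n_over0 <- nrow(over)
  over <- over[over$err_mag <= inf$overacc_error_limit_D &
                 over$threshold_logmar <= inf$overacc_va_limit_logmar, ]
  n_sat_dropped <- n_over0 - nrow(over)
  fit_over <- fit_or_null(over, threshold_logmar ~ err_mag * pupil_c + illuminant,
                          "overaccommodation")

  under <- df[df$error_D < 0, ]
  fit_under <- fit_or_null(under, threshold_logmar ~ err_mag * pupil_c + illuminant,
                           "underaccommodation")

  emm <- NULL
  if (!is.null(fit_lin) && isTRUE(fit_lin$converged)) {
    emm <- tryCatch(
      as.data.frame(emmeans::emmeans(fit_lin$fit, "illuminant",
                                     lmer.df = "asymptotic")),
      error = function(e) NULL)
  }
  list(linear_range = fit_lin, overacc = fit_over, underacc = fit_under,
       emm_linear_range = emm,
       exclusion_counts = c(pupil_below_4mm = n_pupil_dropped,
                            overacc_saturated = n_sat_dropped))
}

#' Restrict trial summaries to the linear portion of each response curve
#'
#' Runs the gradient-based saturation rule on every subject x illuminant
#' curve ([response_curves()]) and drops trials at saturated demands, so
#' downstream model fits use only distances within each subject's
#' accommodative range.
#'
#' @param summaries Trial summaries.
#' @param config A [chromacc_config()].
#' @return The subset of `summaries` on unsaturated points.
#' @export
linear_portion_only <- function(summaries, config = chromacc_config()) {
  df <- as.data.frame(summaries)
  curves <- response_curves(df, config)
  key <- paste(df$subject, df$illuminant, df$distance_D)
  ckey <- paste(curves$subject, curves$illuminant, curves$demand_D)
  sat <- curves$saturated[match(key, ckey)]
  df[!is.na(sat) & !sat, ]
}

#' Stimulus-response curves and their linear portions
#'
#' Aggregates kept trials to the median response per
#' subject x illuminant x distance, runs the gradient-based saturation rule
#' on each curve, and returns one row per point with its `saturated` flag.
#'
#' @param summaries Trial summaries.
#' @param config A [chromacc_config()].
#' @return A data.frame: `subject, illuminant, demand_D, response_D,
#'   median_pupil_mm, saturated, usable`.
#' @export
response_curves <- function(summaries, config = chromacc_config()) {
  df <- as.data.frame(summaries)
  if (!is.null(df$kept)) df <- df[df$kept %in% TRUE, ]
  df <- df[!is.na(df$median_accommodation_D), ]
  out <- lapply(split(df, list(df$subject, df$illuminant), drop = TRUE),
                function(g) {
    agg <- stats::aggregate(
      cbind(response_D = median_accommodation_D,
            median_pupil_mm = median_pupil_mm) ~ distance_D,
      data = g, FUN = stats::median)
    agg <- agg[order(agg$distance_D), ]
    if (nrow(agg) < 2) return(NULL)
    sat <- detect_linear_range(agg$distance_D, agg$response_D,
                               threshold = config$response_curve$saturation_threshold,
                               method = config$response_curve$gradient_method)
    data.frame(subject = g$subject[1], illuminant = g$illuminant[1],
               demand_D = agg$distance_D, response_D = agg$response_D,
               median_pupil_mm = agg$median_pupil_mm,
               saturated = as.logical(sat),
               usable = isTRUE(attr(sat, "usable")),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Stimulus-response-curve mixed model over the linear portion
#'
#' Accommodation as a function of distance x illuminant over the linear
#' portion of each subject's response curves, weighted by the trial weights,
#' with subject random intercept and distance slope. The companion
#' no-interaction fit supports the LRT / AIC model comparison.
#'
#' @param summaries Trial summaries.
#' @param curves Output of [response_curves()] (computed if `NULL`).
#' @param interaction Include the distance x illuminant interaction.
#' @param config A [chromacc_config()].
#' @param ci_level Confidence level.
#' @return A [fit_lmm()] result.
#' @export
fit_srf_model <- function(summaries, curves = NULL, interaction = TRUE,
                          config = chromacc_config(), ci_level = 0.95) {
  df <- resolve_illuminants(as.data.frame(summaries))
  if (!is.null(df$kept)) df <- df[df$kept %in% TRUE, ]
  df <- df[!is.na(df$median_accommodation_D), ]
  curves <- curves %||% response_curves(df, config)
  key <- paste(df$subject, df$illuminant, df$distance_D)
  ckey <- paste(curves$subject, curves$illuminant, curves$demand_D)
  sat <- curves$saturated[match(key, ckey)]
  df <- df[!is.na(sat) & !sat, ]
  df$illuminant <- illuminant_factor(df$illuminant, df$peak_nm, df$broadband)
  fixed <- if (interaction) {
    median_accommodation_D ~ distance_D * illuminant
  } else {
    median_accommodation_D ~ distance_D + illuminant
  }
  wcol <- if ("weight" %in% names(df)) "weight" else NULL
  fit_lmm(fixed, df,
          random = c("(1 + distance_D | subject)", "(1 | subject)"),
          weights = wcol, ci_level = ci_level)
}
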