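#' Chromatic eye model
#'
#' Three-parameter hyperbolic model of the eye's refractive error as a function
#' of wavelength, `D(lambda) = p - q / (lambda - c)` with `lambda` in
#' micrometers. With the default parameters the model crosses zero defocus at
#' the 580 nm reference wavelength; shorter wavelengths focus in front of the
#' retina (negative defocus, less accommodation needed) and longer wavelengths
#' behind it (positive defocus).
#'
#' @param p Dimensionless asymptotic refractive error.
#' @param q Hyperbola scale, um * D.
#' @param c Pole wavelength, um. Must lie below the visible range
#'   (`c < 0.38`) so the model is finite for all visible wavelengths.
#' @param reference_nm Wavelength kept in focus, nm (informational).
#' @return An object of class `chromatic_eye_model`.
#' @examples
#' m <- chromatic_eye_model()
#' chromatic_defocus(650, m) - chromatic_defocus(450, m) # about 1.2 D
#' @export
chromatic_eye_model <- function(p = 1.7312, q = 0.63346, c = 0.21410,
                                reference_nm = 580) {
  stopifnot(is.numeric(p), is.numeric(q), is.numeric(c), length(p) == 1L,
            length(q) == 1L, length(c) == 1L)
  if (c >= 0.38) {
    stop("pole `c` must lie below the visible range (c < 0.38 um)")
  }
  structure(list(p = p, q = q, c = c, reference_nm = reference_nm),
            class = "chromatic_eye_model")
}

#' @export
print.chromatic_eye_model <- function(x, ...) {
  cat(sprintf(
    "Chromatic eye model D(lambda) = %.4f - %.5f/(lambda - %.5f)  [lambda in um]\n",
    x$p, x$q, x$c))
  cat(sprintf("  reference wavelength in focus: %g nm\n", x$reference_nm))
  invisible(x)
}

#' Defocus caused by longitudinal chromatic aberration
#'
#' Evaluates the chromatic eye model at one or more wavelengths. Positive
#' defocus means more accommodation is required (long wavelengths), negative
#' means less (short wavelengths).
#'
#' @param wavelength_nm Wavelength(s), nm. Must lie above the model pole.
#' @param model A [chromatic_eye_model()].
#' @return Defocus in diopters, same length as `wavelength_nm`.
#' @export
chromatic_defocus <- function(wavelength_nm, model = chromatic_eye_model()) {
  stopifnot(is.numeric(wavelength_nm))
  lambda_um <- wavelength_nm / 1000
  if (any(lambda_um <= model$c)) {
    stop("wavelength at or below the model pole (", 1000 * model$c, " nm)")
  }
  model$p - model$q / (lambda_um - model$c)
}

#' Defocus relative to a centering wavelength
#'
#' `chromatic_defocus(wavelength) - chromatic_defocus(center)`. Used as the
#' LCA-defocus regressor when responses are centered on the green illuminant
#' (527.5 nm by convention).
#'
#' @inheritParams chromatic_defocus
#' @param center_nm Centering wavelength, nm.
#' @return Relative defocus in diopters.
#' @export
relative_defocus <- function(wavelength_nm, center_nm = 527.5,
                             model = chromatic_eye_model()) {
  chromatic_defocus(wavelength_nm, model) - chromatic_defocus(center_nm, model)
}

#' Wavelength in focus
#'
#' Wavelength at which the chromatic eye model's defocus is zero. The closed
#' form is `1000 * (c + q / p)` nm; `method = "root"` finds the same value by
#' bracketed root solving (the two agree to well under 0.01 nm).
#'
#' @inheritParams chromatic_defocus
#' @param method `"closed_form"` or `"root"`.
#' @return Wavelength in nm.
#' @export
in_focus_wavelength <- function(model = chromatic_eye_model(),
                                method = c("closed_form", "root")) {
  method <- match.arg(method)
  if (model$p <= 0) stop("no zero crossing: p must be positive")
  closed <- 1000 * (model$c + model$q / model$p)
  if (method == "closed_form") return(closed)
  lo <- 1000 * model$c * (1 + 1e-9) + 1e-6
  hi <- max(2 * closed, 2000)
  stats::uniroot(function(nm) chromatic_defocus(nm, model),
                 lower = lo, upper = hi, tol = 1e-10)$root
}

#' Defocus spread across a narrowband primary's bandwidth
#'
#' Difference in chromatic defocus across the full width at half maximum of a
#' narrowband primary, evaluated symmetrically at `peak +/- fwhm/2`. Because
#' LCA changes faster at short wavelengths, blue primaries show larger spreads
#' than red ones at equal bandwidth.
#'
#' @inheritParams chromatic_defocus
#' @param peak_nm Peak wavelength, nm.
#' @param fwhm_nm Full width at half maximum, nm.
#' @return Non-negative defocus spread in diopters.
#' @export
fwhm_defocus_spread <- function(peak_nm, fwhm_nm,
                                model = chromatic_eye_model()) {
  stopifnot(all(fwhm_nm >= 0))
  chromatic_defocus(peak_nm + fwhm_nm / 2, model) -
    chromatic_defocus(peak_nm - fwhm_nm / 2, model)
}

#' Effective accommodative demand through a trial lens
#'
#' Dioptric demand of a screen at `1/screen_D` meters viewed through a trial
#' lens of power `lens_D` placed `vertex_m` meters in front of the eye:
#' \deqn{P' = P_s [1 + P_l (x - P_s^{-1})] / [1 + P_s P_l (x - P_s^{-1}) x].}
#' With no lens the demand is the screen distance itself.
#'
#' @param screen_D Physical screen distance in diopters (> 0).
#' @param lens_D Trial-lens power in diopters (vectorized).
#' @param vertex_m Lens-to-eye distance in meters (default 3 cm).
#' @return Effective demand in diopters.
#' @export
effective_demand <- function(screen_D, lens_D, vertex_m = 0.03) {
  stopifnot(screen_D > 0, vertex_m >= 0)
  u <- vertex_m - 1 / screen_D
  num <- screen_D * (1 + lens_D * u)
  den <- 1 + screen_D * lens_D * u * vertex_m
  if (any(abs(den) < 1e-12)) stop("singular lens configuration (zero denominator)")
  num / den
}

#' Angular magnification of a trial lens
#'
#' Ratio of the visual angle subtended through the lens to the unaided angle,
#' `1 / [1 + P_s P_l (x - P_s^{-1}) x]`. Used to correct acuity thresholds
#' measured through trial lenses.
#'
#' @inheritParams effective_demand
#' @return Magnification factor (1 with no lens).
#' @export
angular_magnification <- function(screen_D, lens_D, vertex_m = 0.03) {
  stopifnot(screen_D > 0, vertex_m >= 0)
  den <- 1 + screen_D * lens_D * (vertex_m - 1 / screen_D) * vertex_m
  if (any(abs(den) < 1e-12)) stop("singular lens configuration (zero denominator)")
  1 / den
}

#' Convert a Landolt-C gap size to logMAR
#'
#' Converts a gap in degrees of visual angle (optionally corrected for lens
#' magnification) to minutes of arc and takes the base-10 logarithm; 1 arcmin
#' is 0 logMAR.
#'
#' @param gap_deg Gap size in degrees (> 0).
#' @param magnification Angular magnification correction factor (> 0).
#' @return Acuity in logMAR.
#' @export
gap_to_logmar <- function(gap_deg, magnification = 1) {
  if (any(gap_deg <= 0) || any(magnification <= 0)) {
    stop("gap size and magnification must be positive")
  }
  log10(60 * gap_deg * magnification)
}

#' Narrowband (or broadband) illuminant
#'
#' @param name Label, e.g. `"441"` or `"D65"`.
#' @param peak_nm Peak wavelength in nm (visible range); ignored for demand
#'   computation when `broadband = TRUE`.
#' @param fwhm_nm Full width at half maximum in nm (0 allowed for a
#'   broadband-as-reference entry).
#' @param luminance_cdm2 Luminance in cd/m^2 (> 0).
#' @param broadband Logical; broadband illuminants are treated as focused at
#'   the model's reference wavelength (LCA defocus 0).
#' @return An object of class `illuminant`.
#' @export
illuminant <- function(name, peak_nm, fwhm_nm = 0, luminance_cdm2 = 10,
                       broadband = FALSE) {
  stopifnot(peak_nm > 380, peak_nm < 780, fwhm_nm >= 0, luminance_cdm2 > 0)
  structure(list(name = as.character(name), peak_nm = peak_nm,
                 fwhm_nm = fwhm_nm, luminance_cdm2 = luminance_cdm2,
                 broadband = isTRUE(broadband)),
            class = "illuminant")
}

#' @export
print.illuminant <- function(x, ...) {
  cat(sprintf("Illuminant %s: peak %g nm, FWHM %g nm, %g cd/m^2%s\n",
              x$name, x$peak_nm, x$fwhm_nm, x$luminance_cdm2,
              if (x$broadband) " (broadband)" else ""))
  invisible(x)
}

#' Default illuminant registries
#'
#' The LED sets used by the two apparatus profiles: five narrowband LEDs plus
#' a D65-like broadband mix at 10 cd/m^2 (physical-distance experiments), and
#' three AMOLED primaries plus their RGB broadband mix at 15 cd/m^2
#' (trial-lens experiment). Peak wavelengths are as measured after V(lambda)
#' weighting; the screen-primary FWHMs (20/25/28 nm) are measured values,
#' while the LED FWHMs are realistic free parameters.
#'
#' @param experiment 1, 2 (same LED set) or 3 (screen primaries).
#' @return A data.frame with columns `name, peak_nm, fwhm_nm, luminance_cdm2,
#'   broadband`.
#' @export
default_illuminants <- function(experiment = 1) {
  stopifnot(experiment %in% 1:3)
  if (experiment %in% c(1, 2)) {
    data.frame(
      name = c("441", "460", "527", "588", "661", "D65"),
      peak_nm = c(441, 460, 527, 588, 661, 560),
      fwhm_nm = c(18, 22, 30, 15, 20, 0),
      luminance_cdm2 = 10,
      broadband = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(
      name = c("459", "528", "610", "RGB"),
      peak_nm = c(459, 528, 610, 550),
      fwhm_nm = c(20, 25, 28, 0),
      luminance_cdm2 = 15,
      broadband = c(FALSE, FALSE, FALSE, TRUE),
      stringsAsFactors = FALSE
    )
  }
}

#' Accommodative demand for a stimulus under an illuminant
#'
#' Total demand is the dioptric stimulus distance plus the LCA defocus of the
#' illuminant's peak wavelength. Broadband illuminants contribute zero LCA
#' defocus (treated as focused at the reference wavelength).
#'
#' @param distance_D Dioptric stimulus distance (may be an effective demand
#'   through a trial lens).
#' @param illum An [illuminant()], a list/row with `peak_nm` and `broadband`
#'   fields, or a bare numeric peak wavelength in nm.
#' @param model A [chromatic_eye_model()].
#' @return Demand in diopters.
#' @export
demand_for_illuminant <- function(distance_D, illum,
                                  model = chromatic_eye_model()) {
  if (is.numeric(illum)) {
    return(distance_D + chromatic_defocus(illum, model))
  }
  if (isTRUE(illum$broadband)) return(distance_D + 0)
  if (is.null(illum$peak_nm)) stop("illuminant has no peak wavelength")
  distance_D + chromatic_defocus(illum$peak_nm, model)
}
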