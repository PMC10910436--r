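#' Analytic self-check battery
#'
#' Recomputes the desk-scale quantities the chromatic eye model and trial-lens
#' optics imply — the red-blue (650 vs 450 nm) defocus difference, the
#' in-focus wavelength, the defocus spreads across the screen primaries'
#' bandwidths, the trial-lens demand endpoints, and the distance at which LCA
#' compensation reaches unity for the published model coefficients — and
#' compares each against its expected value at the stated rounding.
#'
#' @param model A [chromatic_eye_model()].
#' @param verbose Print one line per check.
#' @return Invisibly, a data.frame `check, value, target, pass` with
#'   attribute `versions`; all checks pass on a default installation.
#' @export
run_checks <- function(model = chromatic_eye_model(), verbose = TRUE) {
  rows <- list()
  add <- function(check, value, target, tol) {
    rows[[length(rows) + 1L]] <<- data.frame(
      check = check, value = value, target = target,
      pass = is.finite(value) && abs(value - target) <= tol + 1e-12,
      stringsAsFactors = FALSE)
  }
  add("red-blue defocus difference 650-450 nm (D, 1 dp)",
      round(chromatic_defocus(650, model) - chromatic_defocus(450, model), 1),
      1.2, 0)
  add("in-focus wavelength, root solve (nm, integer)",
      round(in_focus_wavelength(model, "root")), 580, 0)
  add("defocus spread 459 nm / 20 nm FWHM (D, 2 dp)",
      round(fwhm_defocus_spread(459, 20, model), 2), 0.21, 0)
  add("defocus spread 528 nm / 25 nm FWHM (D, 2 dp)",
      round(fwhm_defocus_spread(528, 25, model), 2), 0.16, 0)
  add("defocus spread 610 nm / 28 nm FWHM (D, 2 dp)",
      round(fwhm_defocus_spread(610, 28, model), 2), 0.11, 0)
  add("-7 D trial-lens demand at 1 m (D, 1 dp)",
      round(effective_demand(1, -7, 0.03), 1), 6.5, 0)
  add("+2 D trial-lens demand at 1 m (D, integer)",
      round(effective_demand(1, 2, 0.03)), -1, 0)
  add("slope-unity distance for a=-0.26, b=0.28 (D, 1 dp)",
      round(slope_unity_distance(-0.26, 0.28), 1), 4.5, 0)
  out <- do.call(rbind, rows)
  attr(out, "versions") <- c(
    chromacc = as.character(utils::packageVersion("chromacc")),
    R = paste(R.version$major, R.version$minor, sep = "."))
  if (verbose) {
    for (i in seq_len(nrow(out))) {
      cat(sprintf("[%s] %s: %g (target %g)\n",
                  if (out$pass[i]) "ok" else "FAIL",
                  out$check[i], out$value[i], out$target[i]))
    }
  }
  invisible(out)
}
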