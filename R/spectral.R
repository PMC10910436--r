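# CIE photopic luminous efficiency V(lambda), 380-780 nm at 5 nm steps.
# Standard published table; used as the default weighting in spectral_summary().
cie_vlambda_table <- function() {
  wl <- seq(380, 780, by = 5)
  v <- c(
    0.0000390, 0.0000640, 0.000120, 0.000217, 0.000396, 0.000640,
    0.00121, 0.00218, 0.00400, 0.00730, 0.0116, 0.01684, 0.0230,
    0.0298, 0.0380, 0.0480, 0.0600, 0.0739, 0.09098, 0.1126,
    0.13902, 0.1693, 0.20802, 0.2586, 0.3230, 0.4073, 0.5030,
    0.6082, 0.7100, 0.7932, 0.8620, 0.91485, 0.9540, 0.9803,
    0.99495, 1.0000, 0.9950, 0.9786, 0.9520, 0.9154, 0.8700,
    0.8163, 0.7570, 0.6949, 0.6310, 0.5668, 0.5030, 0.4412,
    0.3810, 0.3210, 0.2650, 0.2170, 0.1750, 0.1382, 0.1070,
    0.0816, 0.0610, 0.04458, 0.0320, 0.0232, 0.0170, 0.01192,
    0.00821, 0.005723, 0.004102, 0.002929, 0.002091, 0.001484,
    0.001047, 0.000740, 0.000520, 0.000361, 0.000249, 0.000172,
    0.000120, 0.0000848, 0.0000600, 0.0000424, 0.0000300,
    0.0000212, 0.00001499)
  data.frame(wavelength_nm = wl, value = v)
}

# trapezoidal integral over an ascending grid
trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

#' Luminance-weighted summary of a radiance spectrum
#'
#' Multiplies a measured radiance spectral distribution by the luminous
#' efficiency function V(lambda), then reports the peak wavelength and full
#' width at half maximum of the weighted spectrum (half-max crossings found by
#' linear interpolation between samples) and the luminance
#' `Km * integral(V * L)` with `Km = 683 lm/W`.
#'
#' @param wavelength_nm Ascending wavelength grid, nm.
#' @param radiance Non-negative spectral radiance per wavelength
#'   (W sr^-1 m^-2 nm^-1 for luminance in cd/m^2).
#' @param vlambda Optional data.frame with columns `wavelength_nm, value`
#'   giving the efficiency function; defaults to the built-in CIE photopic
#'   table. It is interpolated onto the spectrum grid (zero outside its
#'   support).
#' @param Km Luminous efficacy constant, lm/W.
#' @return A list with `peak_nm`, `fwhm_nm`, `luminance_cdm2`.
#' @examples
#' wl <- seq(400, 520, 1)
#' sp <- exp(-(wl - 459)^2 / (2 * 8.5^2))
#' spectral_summary(wl, sp)$peak_nm
#' @export
spectral_summary <- function(wavelength_nm, radiance, vlambda = NULL,
                             Km = 683) {
  stopifnot(length(wavelength_nm) == length(radiance),
            all(diff(wavelength_nm) > 0), all(radiance >= 0))
  if (all(radiance == 0)) stop("all-zero spectrum")
  if (is.null(vlambda)) vlambda <- cie_vlambda_table()
  v <- stats::approx(vlambda$wavelength_nm, vlambda$value,
                     xout = wavelength_nm, yleft = 0, yright = 0)$y
  w <- radiance * v
  if (all(w == 0)) stop("spectrum does not overlap the efficiency function")
  i_peak <- which.max(w)
  peak <- wavelength_nm[i_peak]
  half <- w[i_peak] / 2

  cross <- function(idx_from, idx_to) {
    # first half-max crossing walking from idx_from toward idx_to
    step <- if (idx_to >= idx_from) 1L else -1L
    for (i in seq(idx_from, idx_to - step, by = step)) {
      j <- i + step
      if ((w[i] - half) * (w[j] - half) <= 0 && w[i] != w[j]) {
        return(wavelength_nm[i] +
                 (half - w[i]) * (wavelength_nm[j] - wavelength_nm[i]) /
                   (w[j] - w[i]))
      }
    }
    wavelength_nm[idx_to]
  }
  lo <- if (i_peak > 1) cross(i_peak, 1L) else wavelength_nm[1]
  hi <- if (i_peak < length(w)) cross(i_peak, length(w)) else
    wavelength_nm[length(w)]
  list(peak_nm = peak,
       fwhm_nm = hi - lo,
       luminance_cdm2 = Km * trapz(wavelength_nm, w))
}
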