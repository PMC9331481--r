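#' Emission channels of the multiphoton FLIM instrument
#'
#' Four detection bands: NAD(P)H autofluorescence (425--475 nm), FAD
#' (502--577 nm), hemoglobin/melanin (600--650 nm) and the collagen
#' second-harmonic band (411--463 nm).
#'
#' @return A tibble with columns `name` and `band_nm`.
#' @export
default_channels <- function() {
  tibble::tibble(
    name    = c("nadh", "fad", "hb_melanin", "shg"),
    band_nm = c("425-475", "502-577", "600-650", "411-463")
  )
}

#' Describe the TCSPC instrument
#'
#' The time-resolved acquisition is modelled by a laser repetition period,
#' a number of histogram bins per period, and a Gaussian instrument
#' response function (IRF). The defaults correspond to an 80 MHz
#' multiphoton system (12.5 ns period) with 256 bins and a 0.15 ns FWHM
#' IRF centred at 1 ns.
#'
#' @param repetition_period Laser period in ns.
#' @param n_bins Number of time bins per period (>= 16).
#' @param irf_fwhm Gaussian IRF full width at half maximum, ns.
#' @param irf_center IRF centre position within the period, ns.
#' @param channels Tibble of emission bands, see [default_channels()].
#' @return An object of class `flim_instrument`.
#' @export
instrument_model <- function(repetition_period = 12.5, n_bins = 256L,
                             irf_fwhm = 0.15, irf_center = 1.0,
                             channels = default_channels()) {
  check_number(repetition_period, "repetition_period", positive = TRUE)
  check_number(irf_fwhm, "irf_fwhm", positive = TRUE)
  check_number(irf_center, "irf_center", nonneg = TRUE)
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 16L) {
    stop_invalid("`n_bins` must be an integer >= 16.", "invalid_argument")
  }
  if (irf_fwhm >= repetition_period) {
    stop_invalid("`irf_fwhm` must be smaller than the repetition period.",
                 "invalid_argument")
  }
  dt <- repetition_period / n_bins
  structure(
    list(
      repetition_period = repetition_period,
      n_bins = n_bins,
      bin_width = dt,
      time_axis = (seq_len(n_bins) - 0.5) * dt,  # bin centres
      irf_fwhm = irf_fwhm,
      irf_center = irf_center,
      channels = channels
    ),
    class = "flim_instrument"
  )
}

#' @export
print.flim_instrument <- function(x, ...) {
  cat(sprintf(
    "<flim_instrument> period %.3g ns, %d bins (%.4g ns/bin), IRF %.3g ns FWHM @ %.3g ns\n",
    x$repetition_period, x$n_bins, x$bin_width, x$irf_fwhm, x$irf_center))
  cat("channels:", paste(x$channels$name, collapse = ", "), "\n")
  invisible(x)
}

#' First-harmonic angular frequency of a repetition period
#'
#' @param repetition_period Laser period in ns.
#' @param harmonic Harmonic number n (default 1).
#' @return omega = 2 * pi * n / period, in 1/ns.
#' @export
angular_frequency <- function(repetition_period, harmonic = 1L) {
  check_number(repetition_period, "repetition_period", positive = TRUE)
  check_number(harmonic, "harmonic", positive = TRUE)
  2 * pi * harmonic / repetition_period
}
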