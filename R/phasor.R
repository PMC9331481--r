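#' Closed-form phasor position of a single lifetime
#'
#' A mono-exponential decay with constant tau maps to
#' g = 1 / (1 + (w tau)^2), s = w tau / (1 + (w tau)^2): a point on the
#' universal circle of centre (1/2, 0) and radius 1/2, running from
#' (1, 0) at tau = 0 toward (0, 0) as tau grows.
#'
#' @param tau Lifetime(s), ns; must be >= 0.
#' @param omega Angular frequency, 1/ns (see [angular_frequency()]).
#' @return Tibble with one row per tau and columns `tau`, `g`, `s`.
#' @export
lifetime_to_phasor <- function(tau, omega) {
  check_number(omega, "omega", positive = TRUE)
  if (any(!is.finite(tau)) || any(tau < 0)) {
    stop_invalid("`tau` must be non-negative and finite.", "invalid_argument")
  }
  wt <- omega * tau
  tibble::tibble(tau = tau, g = 1 / (1 + wt^2), s = wt / (1 + wt^2))
}

#' First-harmonic phasor transform of a decay cube
#'
#' Per pixel, g = sum I(t) cos(n w t) / sum I(t) and
#' s = sum I(t) sin(n w t) / sum I(t), with t the bin centres and
#' w = 2 pi / repetition period. Zero-intensity pixels are flagged
#' invalid rather than propagating NaN. The returned field is
#' uncalibrated: the IRF delay and width demodulate and rotate all
#' phasors by a common complex factor until [calibrate_phasor()] removes
#' it against a reference of known lifetime.
#'
#' @param cube A `decay_cube`.
#' @param harmonic Harmonic number n (default 1).
#' @return An object of class `phasor_field` with matrices `g`, `s`,
#'   `intensity`, logical `valid`, and the harmonic/frequency metadata.
#' @export
phasor_transform <- function(cube, harmonic = 1L) {
  stopifnot(inherits(cube, "decay_cube"))
  check_number(harmonic, "harmonic", positive = TRUE)
  d <- dim(cube$counts)
  if (any(cube$counts < 0)) {
    stop_invalid("decay cube has negative counts.", "invalid_input")
  }
  period <- cube$meta$instrument$repetition_period
  omega <- angular_frequency(period, harmonic)
  t_k <- cube$time_axis
  cw <- cos(omega * t_k); sw <- sin(omega * t_k)
  # accumulate per time-bin slice: avoids coercing the whole cube to double
  g_num <- matrix(0, d[1], d[2])
  s_num <- g_num
  total <- g_num
  for (k in seq_len(d[3])) {
    slice <- cube$counts[, , k]
    g_num <- g_num + cw[k] * slice
    s_num <- s_num + sw[k] * slice
    total <- total + slice
  }
  g_num <- as.vector(g_num); s_num <- as.vector(s_num)
  total <- as.vector(total)
  if (!any(total > 0)) {
    stop_invalid("decay cube is empty: no pixel has any photons.",
                 "invalid_input")
  }
  valid <- total > 0
  g <- ifelse(valid, g_num / total, NA_real_)
  s <- ifelse(valid, s_num / total, NA_real_)
  structure(
    list(g = matrix(g, d[1], d[2]), s = matrix(s, d[1], d[2]),
         intensity = matrix(total, d[1], d[2]),
         valid = matrix(valid, d[1], d[2]),
         harmonic = as.integer(harmonic), omega = omega,
         repetition_period = period, channel = cube$channel,
         calibrated = FALSE,
         meta = list(pixel_size_um = cube$meta$pixel_size_um)),
    class = "phasor_field"
  )
}

#' @export
print.phasor_field <- function(x, ...) {
  cat(sprintf(
    "<phasor_field> channel %s, %d x %d px, harmonic %d, %s\n",
    x$channel, nrow(x$g), ncol(x$g), x$harmonic,
    if (x$calibrated) "calibrated" else "uncalibrated"))
  invisible(x)
}

#' Calibrate a phasor field against a known-lifetime reference
#'
#' Computes the photon-weighted mean phasor of a reference cube of a
#' single known lifetime (acquired/simulated with the same instrument),
#' and applies the rotation-and-scaling that maps it onto the
#' closed-form position [lifetime_to_phasor()] of `reference_tau`. This
#' removes the common IRF demodulation from every pixel.
#'
#' @param field A `phasor_field`.
#' @param reference A `decay_cube` of the uniform reference, or a
#'   `phasor_field` already transformed at the same harmonic.
#' @param reference_tau Known reference lifetime, ns (0 allowed: an SHG
#'   / scatter reference maps to (1, 0)).
#' @return The calibrated `phasor_field`.
#' @export
calibrate_phasor <- function(field, reference, reference_tau) {
  stopifnot(inherits(field, "phasor_field"))
  if (!is.finite(reference_tau) || reference_tau < 0) {
    stop_invalid("`reference_tau` must be >= 0.", "invalid_argument")
  }
  ref_field <- if (inherits(reference, "decay_cube")) {
    phasor_transform(reference, harmonic = field$harmonic)
  } else if (inherits(reference, "phasor_field")) {
    if (reference$harmonic != field$harmonic) {
      stop_invalid("reference harmonic does not match the field.",
                   "invalid_argument")
    }
    reference
  } else {
    stop_invalid("`reference` must be a decay_cube or phasor_field.",
                 "invalid_argument")
  }
  wts <- ref_field$intensity[ref_field$valid]
  if (length(wts) == 0 || sum(wts) <= 0) {
    stop_invalid("reference has no photons.", "invalid_input")
  }
  meas <- complex(real = sum(ref_field$g[ref_field$valid] * wts),
                  imaginary = sum(ref_field$s[ref_field$valid] * wts)) / sum(wts)
  if (Mod(meas) == 0) {
    stop_invalid("reference mean phasor is at the origin; cannot calibrate.",
                 "invalid_input")
  }
  target <- lifetime_to_phasor(reference_tau, field$omega)
  k <- complex(real = target$g, imaginary = target$s) / meas
  z <- complex(real = field$g, imaginary = field$s) * k
  field$g[] <- Re(z)
  field$s[] <- Im(z)
  field$calibrated <- TRUE
  field$calibration <- list(reference_tau = reference_tau,
                            factor = k, reference_phasor = meas)
  field
}

#' Photon-weighted phasor centre of mass
#'
#' @param field A `phasor_field`.
#' @param mask Optional logical matrix selecting pixels (default: all
#'   valid pixels).
#' @param weighted Photon-weighted (default) or unweighted mean.
#' @return One-row tibble: `g`, `s`, `n_pixels`, `total_photons`.
#' @export
phasor_center_of_mass <- function(field, mask = NULL, weighted = TRUE) {
  stopifnot(inherits(field, "phasor_field"))
  sel <- field$valid
  if (!is.null(mask)) {
    if (!is.logical(mask) || !identical(dim(mask), dim(field$g))) {
      stop_invalid("`mask` must be a logical matrix matching the field.",
                   "invalid_argument")
    }
    sel <- sel & mask
  }
  if (!any(sel)) {
    stop_invalid("mask selects no valid pixels.", "empty_mask")
  }
  w <- if (weighted) field$intensity[sel] else rep(1, sum(sel))
  tibble::tibble(
    g = sum(field$g[sel] * w) / sum(w),
    s = sum(field$s[sel] * w) / sum(w),
    n_pixels = sum(sel),
    total_photons = sum(field$intensity[sel])
  )
}

#' Spatial median filter on phasor components
#'
#' Per-component square-window median over valid pixels; intensity is
#' left untouched. Optional denoising step, off by default in the
#' pipeline.
#'
#' @param field A `phasor_field`.
#' @param window Odd window edge length (1 = identity).
#' @return The filtered `phasor_field`.
#' @export
median_filter_phasor <- function(field, window = 3L) {
  stopifnot(inherits(field, "phasor_field"))
  window <- as.integer(window)
  if (is.na(window) || window < 1L || window %% 2L == 0L) {
    stop_invalid("`window` must be an odd integer >= 1.", "invalid_argument")
  }
  if (window == 1L) return(field)
  half <- window %/% 2L
  filt <- function(m) {
    ny <- nrow(m); nx <- ncol(m)
    pad <- matrix(NA_real_, ny + 2L * half, nx + 2L * half)
    pad[half + seq_len(ny), half + seq_len(nx)] <- m
    stack <- array(NA_real_, c(ny, nx, window^2))
    l <- 0L
    for (dy in -half:half) for (dx in -half:half) {
      l <- l + 1L
      stack[, , l] <- pad[half + seq_len(ny) + dy, half + seq_len(nx) + dx]
    }
    apply(stack, c(1, 2), median, na.rm = TRUE)
  }
  g <- field$g; s <- field$s
  g[!field$valid] <- NA_real_
  s[!field$valid] <- NA_real_
  field$g <- filt(g)
  field$s <- filt(s)
  field$g[!field$valid] <- NA_real_
  field$s[!field$valid] <- NA_real_
  field
}
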