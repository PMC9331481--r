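#' Expected per-bin photon fractions for one decay species
#'
#' Forward model of the TCSPC histogram: the periodically wrapped
#' exponential decay (or a zero-lifetime pulse for SHG) is circularly
#' convolved with the Gaussian IRF and integrated over each time bin.
#' The computation is carried out in the Fourier domain with the
#' closed-form coefficients of each factor (wrapped exponential:
#' 1/(1 + i m w0 tau); Gaussian IRF: phase shift times Gaussian
#' attenuation; bin integration: a sinc factor), so every harmonic of
#' the synthesized histogram — in particular the first, which the phasor
#' transform reads out — is exact up to floating point.
#'
#' @param tau Decay constant in ns, or NULL with `instantaneous = TRUE`.
#' @param instrument A [instrument_model()].
#' @param instantaneous TRUE for an IRF-shaped (no decay) pulse.
#' @return Numeric vector of length `n_bins`, non-negative, summing to 1.
#' @export
decay_shape <- function(tau, instrument, instantaneous = FALSE) {
  stopifnot(inherits(instrument, "flim_instrument"))
  if (!instantaneous) check_number(tau, "tau", positive = TRUE)
  N <- instrument$n_bins
  T_rep <- instrument$repetition_period
  w0 <- 2 * pi / T_rep
  sigma <- instrument$irf_fwhm / (2 * sqrt(2 * log(2)))
  m <- seq.int(-(N %/% 2 - 1L), N %/% 2 - 1L)
  decay_fac <- if (instantaneous) rep(1 + 0i, length(m)) else
    1 / (1 + 1i * m * w0 * tau)
  # sub-bin timing jitter (1.5 bin widths) folded into the effective IRF:
  # keeps the synthesized histogram band-limited below the bin Nyquist,
  # hence non-negative; its common first-harmonic factor is removed by
  # phasor calibration like any other instrument response term
  sigma_eff <- sqrt(sigma^2 + (1.5 * instrument$bin_width)^2)
  irf_fac <- exp(-1i * m * w0 * instrument$irf_center -
                   (m * w0 * sigma_eff)^2 / 2)
  x <- m * pi / N
  sinc <- ifelse(m == 0L, 1, sin(x) / x)
  coef <- decay_fac * irf_fac * sinc / N
  k <- seq_len(N) - 0.5
  b <- Re(exp(2i * pi * outer(k / N, m)) %*% coef)[, 1]
  b <- pmax(b, 0)
  b / sum(b)
}

#' Simulate a per-channel TCSPC decay cube over a phantom
#'
#' For each emitting pixel, the noiseless decay is the
#' fractional-intensity-weighted sum of single-exponential decays
#' convolved with the IRF ([decay_shape()]); truth-weighted metabolic
#' species mix their free and bound components according to the
#' per-pixel ground-truth bound fraction. Counts are then Poisson
#' sampled (or returned as rounded expected values in noiseless mode).
#'
#' @param map A [make_phantom()] label map.
#' @param ground_truth Bound-fraction grid from [layer_metabolic_profile()]
#'   (percent; -1 sentinel outside the retina). May be NULL for channels
#'   with no truth-weighted species.
#' @param fluorophores List of [fluorophore_spec()]s, see
#'   [default_fluorophores()].
#' @param instrument A [instrument_model()].
#' @param photons_per_pixel Expected photons per emitting pixel at unit
#'   brightness; must be > 0.
#' @param channel Which emission channel to simulate.
#' @param seed Integer seed for the Poisson sampling.
#' @param poisson FALSE returns the noiseless expected histogram
#'   (rounded to integer counts when `round_counts`).
#' @param round_counts Keep integer counts in noiseless mode (default
#'   FALSE: exact expected values, used by noiseless oracles).
#' @return An object of class `decay_cube`: integer (or numeric) array
#'   `(y, x, time bin)` plus channel, time axis and metadata.
#' @export
simulate_decay_cube <- function(map, ground_truth = NULL,
                                fluorophores = default_fluorophores(),
                                instrument = instrument_model(),
                                photons_per_pixel = 1e4,
                                channel = "nadh", seed = 1L,
                                poisson = TRUE, round_counts = FALSE) {
  stopifnot(inherits(map, "layer_label_map"))
  check_number(photons_per_pixel, "photons_per_pixel", positive = TRUE)
  if (!channel %in% instrument$channels$name) {
    stop_invalid(sprintf("channel '%s' is not in the instrument model.", channel),
                 "configuration_error")
  }
  specs <- Filter(function(f) f$channel == channel, fluorophores)
  bad <- vapply(specs, function(f) !f$channel %in% instrument$channels$name,
                logical(1))
  if (any(bad)) {
    stop_invalid("fluorophore assigned to a channel the instrument lacks.",
                 "configuration_error")
  }
  ny <- nrow(map$labels); nx <- ncol(map$labels)
  N <- instrument$n_bins
  lab <- as.vector(map$labels)
  # which pixels emit in this channel, and their expected histograms
  pix_by_spec <- lapply(specs, function(f) {
    pix <- lab %in% f$tissues
    if (f$truth_weighted) {
      if (is.null(ground_truth)) {
        stop_invalid("channel has a truth-weighted species but no ground truth grid.",
                     "configuration_error")
      }
      pix <- pix & as.vector(ground_truth) >= 0
    }
    which(pix)
  })
  emit <- sort(unique(unlist(pix_by_spec)))
  # per-spec: rows within `emit`, and the per-pixel weight rows (free,
  # bound fractional intensities for truth-weighted species) times the
  # per-component decay shapes; expected counts are assembled chunkwise
  # so no full-image expected matrix is ever held
  contribs <- Map(function(f, pix) {
    rows <- match(pix, emit)
    if (f$truth_weighted) {
      w <- as.vector(ground_truth)[pix] / 100
      shapes <- rbind(decay_shape(f$lifetimes[1], instrument),
                      decay_shape(f$lifetimes[2], instrument))
      wts <- cbind(1 - w, w) * photons_per_pixel * f$brightness
    } else {
      sh <- if (f$instantaneous) {
        decay_shape(NULL, instrument, instantaneous = TRUE)
      } else {
        as.vector(vapply(f$lifetimes, decay_shape, numeric(N),
                         instrument = instrument) %*% f$fractions)
      }
      shapes <- matrix(sh, nrow = 1)
      wts <- matrix(photons_per_pixel * f$brightness,
                    nrow = length(rows), ncol = 1)
    }
    list(rows = rows, wts = wts, shapes = shapes)
  }, specs, pix_by_spec)
  # time-first layout during assembly: chunk writes are then contiguous
  counts_t <- matrix(if (poisson || round_counts) 0L else 0, N, ny * nx)
  if (poisson) withr::local_seed(seed)
  chunk <- 25000L
  for (start in seq_len(max(0L, ceiling(length(emit) / chunk)))) {
    a <- (start - 1L) * chunk + 1L
    b <- min(start * chunk, length(emit))
    E <- matrix(0, N, b - a + 1L)
    for (co in contribs) {
      sel <- which(co$rows >= a & co$rows <= b)
      if (length(sel) == 0) next
      E[, co$rows[sel] - a + 1L] <- E[, co$rows[sel] - a + 1L, drop = FALSE] +
        crossprod(co$shapes, t(co$wts[sel, , drop = FALSE]))
    }
    counts_t[, emit[a:b]] <- if (poisson) {
      rpois(length(E), E)
    } else if (round_counts) {
      as.integer(round(E))
    } else {
      E
    }
  }
  counts <- aperm(array(counts_t, dim = c(N, ny, nx)), c(2, 3, 1))
  rm(counts_t)
  structure(
    list(counts = counts,
         channel = channel,
         time_axis = instrument$time_axis,
         meta = list(pixel_size_um = map$pixel_size_um, seed = seed,
                     photons_per_pixel = photons_per_pixel,
                     poisson = poisson, instrument = instrument)),
    class = "decay_cube"
  )
}

#' @export
print.decay_cube <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<decay_cube> channel %s, %d x %d px, %d time bins, %.4g total photons\n",
              x$channel, d[1], d[2], d[3], sum(x$counts)))
  invisible(x)
}

#' Uniform single-lifetime reference cube for phasor calibration
#'
#' A small field in which every pixel holds the same known
#' mono-exponential decay, simulated with the same instrument (same IRF,
#' binning) as the data it calibrates. Noiseless by default so the
#' calibration factor is exact.
#'
#' @param tau Reference lifetime, ns.
#' @param instrument A [instrument_model()].
#' @param n_pixels Edge length of the square reference field.
#' @param photons_per_pixel Photon budget per pixel.
#' @param poisson Poisson-sample the reference (default FALSE).
#' @param seed Seed when `poisson = TRUE`.
#' @return A `decay_cube` with `meta$reference_tau` set.
#' @export
simulate_reference_cube <- function(tau, instrument = instrument_model(),
                                    n_pixels = 8L, photons_per_pixel = 1e5,
                                    poisson = FALSE, seed = 1L) {
  check_number(tau, "tau", positive = TRUE)
  sh <- decay_shape(tau, instrument)
  N <- instrument$n_bins
  expected <- matrix(photons_per_pixel * sh, nrow = n_pixels^2, ncol = N,
                     byrow = TRUE)
  counts <- if (poisson) {
    withr::local_seed(seed)
    matrix(rpois(length(expected), expected), nrow(expected), N)
  } else {
    expected
  }
  structure(
    list(counts = array(counts, dim = c(n_pixels, n_pixels, N)),
         channel = "reference",
         time_axis = instrument$time_axis,
         meta = list(pixel_size_um = NA_real_, seed = seed,
                     photons_per_pixel = photons_per_pixel,
                     poisson = poisson, instrument = instrument,
                     reference_tau = tau)),
    class = "decay_cube"
  )
}

#' Simulate per-image outer/inner region means
#'
#' Aggregate-level generator used for statistical calibration: each
#' image carries a shared random section effect (fixation, depth and
#' intensity vary between sections) plus independent region residuals,
#' so that the marginal between-image SDs equal `outer_sd`/`inner_sd`.
#'
#' @param n_images Number of images (pairs).
#' @param outer_mean,inner_mean Ground-truth region means, percent.
#' @param outer_sd,inner_sd Marginal between-image SDs, percentage points.
#' @param image_effect_sd SD of the shared per-image effect; must be
#'   smaller than both marginal SDs.
#' @param seed Integer seed.
#' @return Tibble with columns `image_id`, `outer`, `inner`.
#' @export
simulate_region_means <- function(n_images = 86, outer_mean = 58.9,
                                  inner_mean = 60.9, outer_sd = 3.7,
                                  inner_sd = 2.6, image_effect_sd = 2.0,
                                  seed = 1L) {
  check_number(n_images, "n_images", positive = TRUE)
  if (image_effect_sd >= min(outer_sd, inner_sd)) {
    stop_invalid("`image_effect_sd` must be below both marginal SDs.",
                 "invalid_argument")
  }
  withr::local_seed(seed)
  eff <- rnorm(n_images, 0, image_effect_sd)
  tibble::tibble(
    image_id = seq_len(n_images),
    outer = outer_mean + eff +
      rnorm(n_images, 0, sqrt(outer_sd^2 - image_effect_sd^2)),
    inner = inner_mean + eff +
      rnorm(n_images, 0, sqrt(inner_sd^2 - image_effect_sd^2))
  )
}
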