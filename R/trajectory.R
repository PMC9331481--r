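#' Fit a metabolic trajectory through a phasor centre of mass
#'
#' The trajectory is the chord of the universal circle drawn from the
#' free-species anchor (the closed-form position of `free_tau`), through
#' the ROI's phasor centre of mass, extrapolated to its second
#' intersection with the circle — the 100%-bound anchor. A centre of
#' mass that noise has pushed slightly outside the circle is clamped
#' radially (warning beyond `clamp_tol`).
#'
#' @param com Centre of mass: a one-row tibble/list with `g`, `s`
#'   (e.g. from [phasor_center_of_mass()]) or a length-2 numeric.
#' @param free_tau Free-species lifetime anchor, ns (0.4 for NAD(P)H,
#'   2.6 for FAD).
#' @param omega Angular frequency, 1/ns.
#' @param clamp_tol Radial clamp tolerance outside the circle.
#' @return An object of class `flim_trajectory`: `free_anchor` and
#'   `bound_anchor` (named numeric `c(g, s)`, both on the circle),
#'   `free_tau`, `omega`, `chord_length`.
#' @export
fit_trajectory <- function(com, free_tau, omega, clamp_tol = 0.02) {
  com <- as_gs(com)
  check_number(free_tau, "free_tau", nonneg = TRUE)
  check_number(omega, "omega", positive = TRUE)
  centre <- c(g = 0.5, s = 0)
  r <- 0.5
  dist_c <- sqrt(sum((com - centre)^2))
  if (dist_c > r) {
    if (dist_c > r + clamp_tol) {
      rlang::warn(sprintf(
        "centre of mass lies %.4f outside the universal circle; clamped radially.",
        dist_c - r))
    }
    com <- centre + (com - centre) * (r / dist_c)
  }
  fa <- lifetime_to_phasor(free_tau, omega)
  free_anchor <- c(g = fa$g, s = fa$s)
  d <- com - free_anchor
  if (sqrt(sum(d^2)) < 1e-12) {
    stop_invalid("centre of mass coincides with the free anchor; trajectory is degenerate.",
                 "degenerate_trajectory")
  }
  # line through the on-circle free anchor and com: the non-zero root of
  # |A + t d - c|^2 = r^2 gives the second intersection
  t_star <- -2 * sum((free_anchor - centre) * d) / sum(d^2)
  if (abs(t_star) < 1e-12) {
    stop_invalid("trajectory is tangent to the circle at the free anchor.",
                 "degenerate_trajectory")
  }
  bound_anchor <- free_anchor + t_star * d
  structure(
    list(free_anchor = free_anchor, bound_anchor = bound_anchor,
         free_tau = free_tau, omega = omega,
         chord_length = sqrt(sum((bound_anchor - free_anchor)^2))),
    class = "flim_trajectory"
  )
}

#' @export
print.flim_trajectory <- function(x, ...) {
  cat(sprintf(
    "<flim_trajectory> free tau %.3g ns at (%.4f, %.4f) -> bound anchor (%.4f, %.4f), chord %.4f\n",
    x$free_tau, x$free_anchor[["g"]], x$free_anchor[["s"]],
    x$bound_anchor[["g"]], x$bound_anchor[["s"]], x$chord_length))
  invisible(x)
}

as_gs <- function(p) {
  if (is.data.frame(p) || is.list(p)) {
    c(g = as.numeric(p$g)[1], s = as.numeric(p$s)[1])
  } else if (is.numeric(p) && length(p) == 2) {
    c(g = unname(p[1]), s = unname(p[2]))
  } else {
    stop_invalid("expected a phasor point with components g and s.",
                 "invalid_argument")
  }
}

#' Bound percentage along a metabolic trajectory
#'
#' Orthogonal projection of the phasor point onto the chord, expressed
#' as percent of the chord length from the free anchor (0% free anchor,
#' 100% bound anchor), clamped to [0, 100]. This is a fractional
#' *intensity*, which is what phasor linearity measures — not a molar
#' concentration ratio.
#'
#' @param trajectory A [fit_trajectory()] model.
#' @param com Phasor point(s): tibble with columns `g`, `s` (any number
#'   of rows) or a length-2 numeric.
#' @return Numeric vector of bound percentages.
#' @export
bound_fraction <- function(trajectory, com) {
  stopifnot(inherits(trajectory, "flim_trajectory"))
  if (trajectory$chord_length <= 0) {
    stop_invalid("trajectory chord has zero length.", "degenerate_trajectory")
  }
  if (is.data.frame(com)) {
    gs <- cbind(com$g, com$s)
  } else {
    p <- as_gs(com)
    gs <- matrix(p, ncol = 2)
  }
  A <- trajectory$free_anchor
  B <- trajectory$bound_anchor
  u <- B - A
  f <- ((gs[, 1] - A[["g"]]) * u[["g"]] + (gs[, 2] - A[["s"]]) * u[["s"]]) /
    sum(u^2)
  pmin(100, pmax(0, 100 * f))
}

#' Free-FAD percentage along an FAD trajectory
#'
#' Identical chord geometry with the free anchor at tau = 2.6 ns; the
#' FAD channel is conventionally reported as percent *free*, i.e.
#' 100 minus the bound-side fraction.
#'
#' @inheritParams bound_fraction
#' @return Numeric vector of free percentages.
#' @export
fad_free_fraction <- function(trajectory, com) {
  100 - bound_fraction(trajectory, com)
}

#' Per-pixel bound-fraction map
#'
#' Projects every valid pixel of a calibrated field onto a trajectory
#' chord; used for rainbow-map rendering of the metabolic state.
#'
#' @param field A calibrated `phasor_field`.
#' @param trajectory A [fit_trajectory()] model.
#' @return Numeric matrix of bound percentages (NA where invalid).
#' @export
pixel_bound_map <- function(field, trajectory) {
  stopifnot(inherits(field, "phasor_field"))
  out <- matrix(NA_real_, nrow(field$g), ncol(field$g))
  sel <- field$valid & is.finite(field$g) & is.finite(field$s)
  out[sel] <- bound_fraction(trajectory,
                             tibble::tibble(g = field$g[sel], s = field$s[sel]))
  out
}

#' Bound-fraction analysis of a set of ROIs
#'
#' For each ROI: photon-weighted phasor centre of mass over the ROI's
#' unmasked pixels, a metabolic trajectory through that centre of mass
#' (per-ROI by default, mirroring a per-ROI ratiometric slider; a single
#' global trajectory through the pooled centre of mass is available for
#' cross-ROI comparability), and the bound percentage. ROIs fully
#' covered by the exclusion mask are dropped with a message.
#'
#' @param field A calibrated `phasor_field`.
#' @param rois An `roi_set` tibble from [make_rois()].
#' @param free_tau Free-species anchor lifetime, ns.
#' @param exclusion_mask Optional logical matrix of pixels to drop (in
#'   addition to any exclusion already applied by [make_rois()]).
#' @param global_trajectory Use one trajectory through the pooled centre
#'   of mass of all ROI pixels.
#' @param weighted Photon-weighted centres of mass (default).
#' @param report Report `"bound"` percent (NAD(P)H convention) or
#'   `"free"` percent (FAD convention).
#' @return Tibble: `roi_id`, `zone`, `region`, `side`, `bound_pct` (or
#'   `free_pct`), `g_com`, `s_com`, `n_pixels`, `total_photons`.
#' @export
analyze_rois <- function(field, rois, free_tau = 0.4,
                         exclusion_mask = NULL, global_trajectory = FALSE,
                         weighted = TRUE, report = c("bound", "free")) {
  stopifnot(inherits(field, "phasor_field"))
  report <- match.arg(report)
  if (!field$calibrated) {
    rlang::warn("phasor field is uncalibrated; bound fractions will be biased.")
  }
  if (!inherits(rois, "roi_set") || nrow(rois) == 0) {
    stop_invalid("`rois` must be a non-empty roi_set.", "invalid_argument")
  }
  masks <- rois$mask
  if (!is.null(exclusion_mask)) {
    masks <- lapply(masks, function(m) m & !exclusion_mask)
  }
  keep <- vapply(masks, function(m) any(m & field$valid), logical(1))
  if (!any(keep)) {
    stop_invalid("all ROIs are empty after exclusion-mask subtraction.",
                 "empty_result")
  }
  if (any(!keep)) {
    rlang::inform(sprintf("dropping %d fully excluded ROI(s): %s",
                          sum(!keep),
                          paste(rois$roi_id[!keep], collapse = ", ")))
  }
  rois <- rois[keep, ]
  masks <- masks[keep]
  coms <- purrr::map(masks, ~ phasor_center_of_mass(field, .x,
                                                    weighted = weighted))
  traj <- NULL
  if (global_trajectory) {
    pooled <- Reduce(`|`, masks)
    traj <- fit_trajectory(phasor_center_of_mass(field, pooled,
                                                 weighted = weighted),
                           free_tau, field$omega)
  }
  res <- purrr::map2_dfr(seq_along(masks), coms, function(i, com) {
    tr <- traj %||% fit_trajectory(com, free_tau, field$omega)
    pct <- bound_fraction(tr, com)
    tibble::tibble(
      roi_id = rois$roi_id[i], zone = rois$zone[i],
      region = rois$region[i], side = rois$side[i],
      bound_pct = pct,
      g_com = com$g, s_com = com$s,
      n_pixels = com$n_pixels, total_photons = com$total_photons
    )
  })
  if (report == "free") {
    res <- dplyr::rename(res, free_pct = "bound_pct")
    res$free_pct <- 100 - res$free_pct
  }
  res
}
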