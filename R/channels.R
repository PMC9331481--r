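#' Define a phasor-position selector
#'
#' Structural species (melanin, hemoglobin, SHG collagen) occupy
#' distinct positions on the phasor plot; a selector is a reference
#' point with a Euclidean selection radius in (g, s) and an intensity
#' floor that suppresses background pixels.
#'
#' @param g,s Reference phasor coordinates.
#' @param radius Selection radius in phasor units (> 0; `Inf` allowed).
#' @param name Selector name (`"melanin"`, `"hemoglobin"`, `"shg"`, or
#'   custom).
#' @param channel Emission channel the selector applies to (optional).
#' @param intensity_floor Minimum photons per pixel (default 5).
#' @return An object of class `phasor_selector`.
#' @export
phasor_selector <- function(g, s, radius, name = "custom",
                            channel = NA_character_, intensity_floor = 5) {
  check_number(g, "g"); check_number(s, "s")
  if (!is.numeric(radius) || length(radius) != 1 || is.na(radius) ||
      radius < 0) {
    stop_invalid("`radius` must be a single non-negative number.",
                 "invalid_argument")
  }
  check_number(intensity_floor, "intensity_floor", nonneg = TRUE)
  structure(
    list(reference = c(g = g, s = s), radius = radius, name = name,
         channel = channel, intensity_floor = intensity_floor),
    class = "phasor_selector"
  )
}

#' @export
print.phasor_selector <- function(x, ...) {
  cat(sprintf("<phasor_selector> %s: (%.4f, %.4f) r=%.4g, floor %g photons\n",
              x$name, x$reference[["g"]], x$reference[["s"]], x$radius,
              x$intensity_floor))
  invisible(x)
}

#' Selector at the closed-form phasor position of a species
#'
#' @param spec A [fluorophore_spec()].
#' @param omega Angular frequency, 1/ns.
#' @param radius Selection radius.
#' @param fractions Free/bound fractional intensities for truth-weighted
#'   species.
#' @param intensity_floor Minimum photons per pixel.
#' @return A `phasor_selector` named after the species.
#' @export
selector_from_spec <- function(spec, omega, radius = 0.05,
                               fractions = NULL, intensity_floor = 5) {
  p <- species_phasor(spec, omega, fractions)
  phasor_selector(p$g, p$s, radius, name = spec$name,
                  channel = spec$channel, intensity_floor = intensity_floor)
}

#' Select pixels by phasor position
#'
#' Mask of pixels whose (g, s) lies within the selector radius of the
#' reference position and whose intensity clears the floor. Mirrors a
#' phasor-plot ROI selection tool: pick a position, highlight every
#' image pixel whose lifetime signature sits there.
#'
#' @param field A calibrated `phasor_field`.
#' @param selector A [phasor_selector()].
#' @return Logical matrix (an empty mask is allowed).
#' @export
phasor_select <- function(field, selector) {
  stopifnot(inherits(field, "phasor_field"),
            inherits(selector, "phasor_selector"))
  if (!field$calibrated) {
    rlang::warn("selecting on an uncalibrated phasor field.")
  }
  d2 <- (field$g - selector$reference[["g"]])^2 +
    (field$s - selector$reference[["s"]])^2
  mask <- field$valid & field$intensity >= selector$intensity_floor &
    !is.na(d2) & d2 < selector$radius^2
  mask[is.na(mask)] <- FALSE
  mask
}

#' Second-harmonic-generation mask
#'
#' SHG is effectively instantaneous, so its phasor sits at the
#' zero-lifetime point (1, 0) — far from any autofluorescence decay.
#' Selecting around (1, 0) separates collagen second-harmonic signal
#' from collagen autofluorescence.
#'
#' @param field A calibrated SHG-channel `phasor_field`.
#' @param radius Selection radius (default 0.05).
#' @param intensity_floor Minimum photons per pixel.
#' @return Logical matrix.
#' @export
shg_mask <- function(field, radius = 0.05, intensity_floor = 5) {
  phasor_select(field, phasor_selector(1, 0, radius, name = "shg",
                                       channel = field$channel,
                                       intensity_floor = intensity_floor))
}

#' Learn a selector from a seed ROI
#'
#' Takes the photon-weighted phasor centre of mass of a seed region
#' (e.g. a hand-drawn ROI over one blood vessel) as the reference, and
#' a quantile of the seed pixels' phasor distances from it as the
#' radius, so the selector generalises to the other structures of the
#' same species.
#'
#' @param field A calibrated `phasor_field`.
#' @param seed_mask Logical matrix marking the seed ROI.
#' @param name Selector name.
#' @param radius_quantile Quantile of seed distances used as the radius
#'   (default 0.95).
#' @param intensity_floor Minimum photons per pixel.
#' @param weighted Photon-weighted centre of mass (default).
#' @return A `phasor_selector`.
#' @export
learn_selector <- function(field, seed_mask, name = "custom",
                           radius_quantile = 0.95, intensity_floor = 5,
                           weighted = TRUE) {
  stopifnot(inherits(field, "phasor_field"))
  com <- phasor_center_of_mass(field, seed_mask, weighted = weighted)
  sel <- field$valid & seed_mask
  d <- sqrt((field$g[sel] - com$g)^2 + (field$s[sel] - com$s)^2)
  radius <- unname(quantile(d, radius_quantile))
  if (radius == 0) {
    rlang::warn("seed ROI phasors are identical; learned radius is 0.")
  }
  phasor_selector(com$g, com$s, radius, name = name,
                  channel = field$channel, intensity_floor = intensity_floor)
}

#' Precision and recall of a mask against ground-truth labels
#'
#' Convenience for phantom validation: compares a selector mask with the
#' set of pixels carrying the given tissue codes.
#'
#' @param mask Logical matrix from [phasor_select()].
#' @param map A `layer_label_map`.
#' @param tissue_codes Integer codes regarded as ground-truth positive.
#' @return One-row tibble: `precision`, `recall`, `n_true`, `n_selected`.
#' @export
mask_accuracy <- function(mask, map, tissue_codes) {
  truth <- matrix(map$labels %in% tissue_codes, nrow(map$labels))
  tp <- sum(mask & truth)
  tibble::tibble(
    precision = if (sum(mask) > 0) tp / sum(mask) else NA_real_,
    recall = if (sum(truth) > 0) tp / sum(truth) else NA_real_,
    n_true = sum(truth), n_selected = sum(mask)
  )
}
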