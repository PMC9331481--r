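#' Define an endogenous fluorophore (or SHG scatterer)
#'
#' A species is one or two exponential decay components with fractional
#' intensities, assigned to an emission channel and to a set of tissue
#' label codes. Second-harmonic generation is effectively instantaneous
#' and is flagged rather than given a lifetime. For the two metabolic
#' species (NAD(P)H, FAD) the free/bound fractional intensities are not
#' fixed here but taken per pixel from a ground-truth bound-fraction
#' grid (`truth_weighted = TRUE`); `lifetimes` is then `c(free, bound)`.
#'
#' @param name Species name.
#' @param lifetimes One or two decay constants tau in ns (NULL for SHG).
#' @param fractions Fractional intensities, summing to 1 (ignored when
#'   `truth_weighted`).
#' @param channel Emission channel name (see [default_channels()]).
#' @param tissues Integer tissue codes that carry this species (see
#'   [retina_layer_codes()]).
#' @param brightness Mean photons per pixel relative to the simulation's
#'   `photons_per_pixel` budget.
#' @param instantaneous TRUE for SHG: an IRF-shaped, zero-lifetime pulse.
#' @param truth_weighted TRUE when per-pixel free/bound weights come from
#'   a ground-truth grid.
#' @return An object of class `fluorophore_spec`.
#' @export
fluorophore_spec <- function(name, lifetimes = NULL, fractions = NULL,
                             channel, tissues = integer(),
                             brightness = 1, instantaneous = FALSE,
                             truth_weighted = FALSE) {
  check_number(brightness, "brightness", positive = TRUE)
  if (instantaneous) {
    if (!is.null(lifetimes)) {
      stop_invalid("an instantaneous (SHG) species carries no lifetime.",
                   "invalid_argument")
    }
  } else {
    if (is.null(lifetimes) || !length(lifetimes) %in% 1:2 ||
        any(!is.finite(lifetimes)) || any(lifetimes <= 0)) {
      stop_invalid("`lifetimes` must be one or two positive tau values (ns).",
                   "invalid_argument")
    }
    if (truth_weighted) {
      if (length(lifetimes) != 2) {
        stop_invalid("a truth-weighted species needs c(free, bound) lifetimes.",
                     "invalid_argument")
      }
      fractions <- c(NA_real_, NA_real_)  # per-pixel, from the truth grid
    } else {
      if (is.null(fractions)) fractions <- rep(1 / length(lifetimes),
                                               length(lifetimes))
      if (length(fractions) != length(lifetimes) ||
          any(fractions < 0) || any(fractions > 1) ||
          abs(sum(fractions) - 1) > 1e-8) {
        stop_invalid("`fractions` must lie in [0,1] and sum to 1.",
                     "invalid_argument")
      }
    }
  }
  structure(
    list(name = name, lifetimes = lifetimes, fractions = fractions,
         channel = channel, tissues = as.integer(tissues),
         brightness = brightness, instantaneous = instantaneous,
         truth_weighted = truth_weighted),
    class = "fluorophore_spec"
  )
}

#' Default fluorophore table for the retina-section phantom
#'
#' NAD(P)H: free tau 0.4 ns, bound tau 3.2 ns, per-pixel weights from the
#' bound-fraction ground truth, emitted by the neural retina layers.
#' FAD: free tau 2.6 ns, bound tau 0.3 ns, likewise truth-weighted.
#' Melanin: short bi-exponential (0.1/1.0 ns) in RPE and choroid.
#' Hemoglobin: very short mono-exponential (0.05 ns) in vessel lumina and
#' the two RPE hemoglobin bands. Collagen SHG: instantaneous, scleral.
#'
#' @param tau_bound_nadh Bound-NAD(P)H lifetime, ns.
#' @param tau_bound_fad Bound-FAD lifetime, ns.
#' @param tau_melanin Two melanin component lifetimes, ns.
#' @param tau_hemoglobin Hemoglobin lifetime, ns.
#' @return Named list of [fluorophore_spec()] objects.
#' @export
default_fluorophores <- function(tau_bound_nadh = 3.2, tau_bound_fad = 0.3,
                                 tau_melanin = c(0.1, 1.0),
                                 tau_hemoglobin = 0.05) {
  codes <- retina_layer_codes()
  retina <- unname(codes[c("OS", "IS", "ONL", "OPL", "INL", "IPL",
                           "GCL", "RNFL")])
  list(
    nadh = fluorophore_spec("nadh", c(0.4, tau_bound_nadh),
                            channel = "nadh", tissues = retina,
                            truth_weighted = TRUE),
    fad = fluorophore_spec("fad", c(2.6, tau_bound_fad),
                           channel = "fad", tissues = retina,
                           truth_weighted = TRUE),
    melanin = fluorophore_spec("melanin", tau_melanin, c(0.5, 0.5),
                               channel = "hb_melanin",
                               tissues = unname(codes[c("choroid", "RPE")])),
    hemoglobin = fluorophore_spec("hemoglobin", tau_hemoglobin,
                                  channel = "hb_melanin",
                                  tissues = unname(codes[c("vessel_lumen",
                                                           "rpe_basal_hb",
                                                           "rpe_apical_hb")])),
    collagen_shg = fluorophore_spec("collagen_shg", channel = "shg",
                                    tissues = unname(codes["sclera"]),
                                    instantaneous = TRUE)
  )
}

#' Closed-form phasor of a fluorophore species
#'
#' Fractional-intensity-weighted combination of the component phasors on
#' the universal circle; an instantaneous species sits at (1, 0).
#'
#' @param spec A [fluorophore_spec()].
#' @param omega Angular frequency, 1/ns.
#' @param fractions Override fractional intensities (needed for
#'   truth-weighted species, e.g. `c(free, bound)` weights).
#' @return A one-row tibble with columns `g`, `s`.
#' @export
species_phasor <- function(spec, omega, fractions = NULL) {
  if (spec$instantaneous) return(tibble::tibble(g = 1, s = 0))
  fr <- fractions %||% spec$fractions
  if (anyNA(fr)) {
    stop_invalid("truth-weighted species: supply `fractions = c(free, bound)`.",
                 "invalid_argument")
  }
  pts <- lifetime_to_phasor(spec$lifetimes, omega)
  tibble::tibble(g = sum(fr * pts$g), s = sum(fr * pts$s))
}
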