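# Shared fixtures, built in code and memoised per test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

std_instrument <- function() memo("inst", instrument_model())

std_omega <- function(harmonic = 1L) {
  angular_frequency(std_instrument()$repetition_period, harmonic)
}

std_reference <- function() {
  memo("ref", simulate_reference_cube(1.0, std_instrument()))
}

# a compact phantom: one peripapillary zone per side
small_phantom <- function(seed = 7L) {
  memo(paste0("phantom", seed),
       make_phantom(width_um = 600, height_um = 300, pixel_size_um = 2,
                    seed = seed))
}

# hand-built decay cube with an explicit time axis (e.g. starting at 0)
raw_cube <- function(counts, time_axis,
                     instrument = std_instrument(), channel = "test") {
  if (is.matrix(counts)) counts <- array(counts, c(1, nrow(counts), ncol(counts)))
  structure(
    list(counts = counts, channel = channel, time_axis = time_axis,
         meta = list(pixel_size_um = 1, seed = NA, photons_per_pixel = NA,
                     poisson = FALSE, instrument = instrument)),
    class = "decay_cube")
}

# noiseless mono-exponential cube sampled on the standard bin centres
mono_cube <- function(tau, instrument = std_instrument(), n_pixels = 2L,
                      photons = 1e5) {
  simulate_reference_cube(tau, instrument, n_pixels = n_pixels,
                          photons_per_pixel = photons)
}

calibrated_field <- function(cube, instrument = std_instrument(),
                             harmonic = 1L, reference_tau = 1.0) {
  ref <- simulate_reference_cube(reference_tau, instrument)
  calibrate_phasor(phasor_transform(cube, harmonic), ref, reference_tau)
}

# per-region recovery of one simulated phantom image (NAD(P)H channel)
recover_regions <- function(map, outer = 58.9, inner = 60.9,
                            photons = 1e5, seed = 1L) {
  gt <- layer_metabolic_profile(map, outer, inner)
  cube <- simulate_decay_cube(map, gt, photons_per_pixel = photons,
                              channel = "nadh", seed = seed)
  fld <- calibrate_phasor(phasor_transform(cube), std_reference(), 1.0)
  rois <- suppressWarnings(make_rois(build_zones(map)))
  res <- analyze_rois(fld, rois, free_tau = 0.4)
  c(outer = mean(res$bound_pct[res$region == "outer"]),
    inner = mean(res$bound_pct[res$region == "inner"]))
}
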