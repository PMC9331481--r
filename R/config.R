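#' Default pipeline configuration
#'
#' A nested list describing one end-to-end run: instrument, phantom
#' geometry, ground-truth metabolic settings, which channels to
#' simulate, analysis parameters and the statistics block. All physical
#' quantities are in the units of their key names (um, ns, photons).
#' This list doubles as the configuration schema: [validate_config()]
#' rejects unknown keys at any level.
#'
#' @param seed Root seed; every stage seed is derived from it.
#' @param n_images Number of phantom images to simulate.
#' @param photons_per_pixel Photon budget per emitting pixel.
#' @return A `pipeline_config` list.
#' @export
default_config <- function(seed = 1L, n_images = 1L,
                           photons_per_pixel = 1e5) {
  structure(
    list(
      seed = as.integer(seed),
      n_images = as.integer(n_images),
      instrument = list(repetition_period_ns = 12.5, n_bins = 256L,
                        irf_fwhm_ns = 0.15, irf_center_ns = 1.0),
      phantom = list(width_um = 3260, height_um = 300, pixel_size_um = 2,
                     disc_width_um = 60, vessel_density = 1,
                     axis = "superior-inferior"),
      truth = list(outer_bound_pct = 58.9, inner_bound_pct = 60.9,
                   jitter_sd = 0, fad_free_pct = 75.3,
                   tau_bound_nadh_ns = 3.2, tau_bound_fad_ns = 0.3,
                   tau_melanin_ns = c(0.1, 1.0), tau_hemoglobin_ns = 0.05),
      channels = c("nadh", "fad", "hb_melanin", "shg"),
      photons_per_pixel = photons_per_pixel,
      analysis = list(harmonic = 1L, roi_width_um = 150,
                      free_tau_nadh_ns = 0.4, free_tau_fad_ns = 2.6,
                      calibration_tau_ns = 1.0, selector_radius = 0.05,
                      intensity_floor = 5, median_filter_window = 1L,
                      global_trajectory = FALSE, eccentricity = "arc"),
      stats = list(pairing = "image", alpha = 0.05),
      verbose = FALSE
    ),
    class = "pipeline_config"
  )
}

#' Validate a pipeline configuration
#'
#' Checks the nested structure against [default_config()] (unknown keys
#' are rejected), fills omitted keys with defaults, and checks basic
#' value sanity. A configuration without a `fad` channel simply skips
#' the FAD outputs.
#'
#' @param config Named list (e.g. from [read_config()]).
#' @return A complete, validated `pipeline_config`.
#' @export
validate_config <- function(config) {
  ref <- unclass(default_config())
  merge_checked <- function(user, def, path) {
    unknown <- setdiff(names(user), names(def))
    if (length(unknown) > 0) {
      stop_invalid(sprintf("unknown config key(s) %s under '%s'.",
                           paste(sQuote(unknown), collapse = ", "), path),
                   "invalid_config")
    }
    for (k in names(user)) {
      if (is.list(def[[k]]) && !is.null(names(def[[k]]))) {
        def[[k]] <- merge_checked(user[[k]], def[[k]],
                                  paste(path, k, sep = "/"))
      } else {
        def[[k]] <- user[[k]]
      }
    }
    def
  }
  cfg <- merge_checked(unclass(config), ref, "config")
  check_number(cfg$seed, "seed")
  check_number(cfg$n_images, "n_images", positive = TRUE)
  check_number(cfg$photons_per_pixel, "photons_per_pixel", positive = TRUE)
  bad <- setdiff(cfg$channels, default_channels()$name)
  if (length(bad) > 0) {
    stop_invalid(sprintf("unknown channel(s): %s.",
                         paste(bad, collapse = ", ")), "invalid_config")
  }
  if (!"nadh" %in% cfg$channels) {
    stop_invalid("the 'nadh' channel is required.", "invalid_config")
  }
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration (YAML)
#'
#' @param path YAML file path.
#' @return [read_config()]: a validated `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stop_invalid(sprintf("config file '%s' not found.", path),
                 "invalid_config")
  }
  validate_config(yaml::read_yaml(path))
}

#' @rdname read_config
#' @param config A `pipeline_config`.
#' @return [write_config()]: `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(config), tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}
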