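# On-disk formats: multi-page TIFF + JSON sidecar for cubes and phasor
# fields, single-page TIFF + JSON legend for label maps, 8-bit TIFF for
# masks, CSV for tables. Integer data round-trips bit-exactly; float
# pages are stored affinely rescaled into [0, 1] as 32-bit floats with
# the offset/scale recorded in the sidecar (~float32 relative precision).

sidecar_path <- function(path) sub("\\.tiff?$", ".json", path)

read_sidecar <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) {
    stop_invalid(sprintf("missing JSON sidecar '%s'.", sc), "malformed_sidecar")
  }
  jsonlite::read_json(sc, simplifyVector = TRUE)
}

safe_read_tiff <- function(path, ...) {
  tryCatch(tiff::readTIFF(path, all = TRUE, ...),
           error = function(e) {
             stop_invalid(sprintf("cannot read TIFF '%s': %s", path,
                                  conditionMessage(e)), "corrupt_tiff")
           })
}

#' Write / read a decay cube (multi-page 16-bit TIFF + JSON sidecar)
#'
#' One TIFF page per time bin, 16-bit counts; the sidecar records the
#' channel, time axis, pixel size, instrument snapshot and seed.
#'
#' @param cube A `decay_cube`.
#' @param path TIFF path (`.tif`); the sidecar takes the same stem.
#' @return `path`, invisibly.
#' @export
write_decay_cube <- function(cube, path) {
  stopifnot(inherits(cube, "decay_cube"))
  cts <- cube$counts
  if (any(cts < 0) || max(cts) > 65535) {
    stop_invalid("counts outside the 16-bit range [0, 65535].",
                 "invalid_input")
  }
  pages <- lapply(seq_len(dim(cts)[3]),
                  function(k) cts[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  inst <- cube$meta$instrument
  jsonlite::write_json(
    list(kind = "decay_cube", channel = cube$channel,
         time_axis = cube$time_axis,
         pixel_size_um = cube$meta$pixel_size_um,
         seed = cube$meta$seed,
         photons_per_pixel = cube$meta$photons_per_pixel,
         dims = dim(cts),
         instrument = list(repetition_period = inst$repetition_period,
                           n_bins = inst$n_bins, irf_fwhm = inst$irf_fwhm,
                           irf_center = inst$irf_center)),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_decay_cube
#' @export
read_decay_cube <- function(path) {
  meta <- read_sidecar(path)
  if (is.null(meta$time_axis)) {
    stop_invalid("sidecar lacks the time axis.", "malformed_sidecar")
  }
  pages <- safe_read_tiff(path, as.is = TRUE)
  if (length(pages) != meta$dims[3] ||
      !all(dim(pages[[1]]) == meta$dims[1:2])) {
    stop_invalid("TIFF shape does not match sidecar metadata.",
                 "shape_mismatch")
  }
  counts <- array(0L, dim = meta$dims)
  for (k in seq_along(pages)) counts[, , k] <- pages[[k]]
  inst <- instrument_model(meta$instrument$repetition_period,
                           meta$instrument$n_bins,
                           meta$instrument$irf_fwhm,
                           meta$instrument$irf_center)
  structure(
    list(counts = counts, channel = meta$channel,
         time_axis = as.numeric(meta$time_axis),
         meta = list(pixel_size_um = meta$pixel_size_um, seed = meta$seed,
                     photons_per_pixel = meta$photons_per_pixel,
                     poisson = TRUE, instrument = inst)),
    class = "decay_cube"
  )
}

#' Write / read a phasor field (32-bit float TIFF + JSON sidecar)
#'
#' Three pages: g, s and intensity, each affinely rescaled into [0, 1]
#' with per-page offset/scale recorded in the sidecar.
#'
#' @param field A `phasor_field`.
#' @param path TIFF path.
#' @return `path`, invisibly.
#' @export
write_phasor_field <- function(field, path) {
  stopifnot(inherits(field, "phasor_field"))
  enc <- function(m) {
    m[!is.finite(m)] <- 0
    lo <- min(m); hi <- max(m)
    scale <- if (hi > lo) hi - lo else 1
    list(page = (m - lo) / scale, offset = lo, scale = scale)
  }
  eg <- enc(field$g); es <- enc(field$s); ei <- enc(field$intensity)
  tiff::writeTIFF(list(eg$page, es$page, ei$page), path,
                  bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(
    list(kind = "phasor_field", channel = field$channel,
         harmonic = field$harmonic,
         repetition_period = field$repetition_period,
         calibrated = field$calibrated,
         pixel_size_um = field$meta$pixel_size_um,
         dims = dim(field$g),
         pages = list(g = list(offset = eg$offset, scale = eg$scale),
                      s = list(offset = es$offset, scale = es$scale),
                      intensity = list(offset = ei$offset, scale = ei$scale))),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_phasor_field
#' @export
read_phasor_field <- function(path) {
  meta <- read_sidecar(path)
  pages <- safe_read_tiff(path)
  if (length(pages) != 3 || !all(dim(pages[[1]]) == meta$dims)) {
    stop_invalid("TIFF shape does not match sidecar metadata.",
                 "shape_mismatch")
  }
  dec <- function(page, info) page * info$scale + info$offset
  g <- dec(pages[[1]], meta$pages$g)
  s <- dec(pages[[2]], meta$pages$s)
  intensity <- dec(pages[[3]], meta$pages$intensity)
  valid <- intensity > 0
  g[!valid] <- NA_real_; s[!valid] <- NA_real_
  structure(
    list(g = g, s = s, intensity = intensity, valid = valid,
         harmonic = as.integer(meta$harmonic),
         omega = angular_frequency(meta$repetition_period, meta$harmonic),
         repetition_period = meta$repetition_period,
         channel = meta$channel, calibrated = isTRUE(meta$calibrated),
         meta = list(pixel_size_um = meta$pixel_size_um)),
    class = "phasor_field"
  )
}

#' Write / read a layer label map (16-bit TIFF + JSON legend)
#'
#' Page 1: integer tissue codes; page 2: the exclusion mask (0/1). The
#' sidecar carries the legend, pixel size, disc position and axis.
#'
#' @param map A `layer_label_map`.
#' @param path TIFF path.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(map, path) {
  stopifnot(inherits(map, "layer_label_map"))
  tiff::writeTIFF(list(map$labels / 65535, (map$exclusion_mask * 1) / 65535),
                  path, bits.per.sample = 16L, reduce = FALSE)
  jsonlite::write_json(
    list(kind = "layer_label_map", legend = as.list(map$legend),
         pixel_size_um = map$pixel_size_um,
         disc_position = as.list(map$disc_position), axis = map$axis,
         dims = dim(map$labels)),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  meta <- read_sidecar(path)
  pages <- safe_read_tiff(path, as.is = TRUE)
  if (!all(dim(pages[[1]]) == meta$dims)) {
    stop_invalid("TIFF shape does not match sidecar metadata.",
                 "shape_mismatch")
  }
  excl <- if (length(pages) >= 2) pages[[2]] > 0 else
    matrix(FALSE, nrow(pages[[1]]), ncol(pages[[1]]))
  structure(
    list(labels = pages[[1]], pixel_size_um = meta$pixel_size_um,
         disc_position = c(x = meta$disc_position$x,
                           y = meta$disc_position$y),
         exclusion_mask = excl, axis = meta$axis,
         legend = unlist(meta$legend),
         width_um = ncol(pages[[1]]) * meta$pixel_size_um,
         height_um = nrow(pages[[1]]) * meta$pixel_size_um),
    class = "layer_label_map"
  )
}

#' Write a binary mask as 8-bit TIFF
#' @param mask Logical matrix.
#' @param path TIFF path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  tiff::writeTIFF((mask * 1), path, bits.per.sample = 8L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  safe_read_tiff(path)[[1]] > 0
}
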