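#' Tissue label codes of the retina-section phantom
#'
#' Integer codes for every tissue class in the label map, from the
#' sclera outward through the retinal pigment epithelium (RPE) and the
#' neural retina (photoreceptor outer/inner segments OS/IS, outer
#' nuclear layer ONL, outer plexiform layer OPL, inner nuclear layer
#' INL, inner plexiform layer IPL, ganglion cell layer GCL, retinal
#' nerve fiber layer RNFL), plus the optic disc, vessel lumina and the
#' basal/apical RPE hemoglobin bands.
#'
#' @return Named integer vector of codes.
#' @export
retina_layer_codes <- function() {
  c(background = 0L, sclera = 1L, choroid = 2L, RPE = 3L,
    OS = 4L, IS = 5L, ONL = 6L, OPL = 7L, INL = 8L, IPL = 9L,
    GCL = 10L, RNFL = 11L, optic_disc = 12L, vessel_lumen = 13L,
    rpe_basal_hb = 14L, rpe_apical_hb = 15L)
}

#' Layer codes of the outer and inner retina
#'
#' The outer retina comprises the photoreceptor segments and the outer
#' nuclear layer; the inner retina runs from the outer plexiform layer
#' to the nerve fiber layer. The RPE belongs to neither region.
#'
#' @return Named list with integer vectors `outer` and `inner`.
#' @export
region_layer_codes <- function() {
  codes <- retina_layer_codes()
  list(outer = unname(codes[c("OS", "IS", "ONL")]),
       inner = unname(codes[c("OPL", "INL", "IPL", "GCL", "RNFL")]))
}

#' Default layer thicknesses (micrometres)
#'
#' Approximate mouse retina cross-section thicknesses, sclera to RNFL.
#'
#' @return Named numeric vector, um.
#' @export
default_layer_thicknesses <- function() {
  c(sclera = 40, choroid = 30, RPE = 10, OS = 25, IS = 20, ONL = 55,
    OPL = 15, INL = 30, IPL = 40, GCL = 18, RNFL = 12)
}

#' Generate a labeled retina-section phantom
#'
#' Builds a straight, horizontally layered retina cross-section: sclera
#' at the bottom, then choroid, RPE (with 1-pixel basal and apical
#' hemoglobin bands), photoreceptor segments, the nuclear and plexiform
#' layers up to the RNFL, and vitreous (background) above. An optic disc
#' interrupts the retina at the section centre; three vascular plexuses
#' are seeded as vessel-lumen disks (deep plexus in the OPL, superficial
#' capillary plexus at the INL/IPL junction, larger retinal vessels in
#' the GCL).
#'
#' @param width_um,height_um Phantom extent, um.
#' @param pixel_size_um Pixel pitch, um.
#' @param layer_thicknesses_um Named vector as [default_layer_thicknesses()].
#' @param disc_width_um Optic disc width, um.
#' @param vessel_density Relative density of vessel lumina (0 disables).
#' @param axis Section axis: `"superior-inferior"` or `"nasal-temporal"`.
#' @param exclusion_mask Optional logical matrix of pixels to exclude
#'   (artifacts, folds); defaults to none.
#' @param seed Integer seed for vessel placement.
#' @return An object of class `layer_label_map`: integer label matrix
#'   (rows = y, top to bottom), pixel size, disc position, exclusion
#'   mask, section axis and code legend.
#' @export
make_phantom <- function(width_um = 3260, height_um = 300, pixel_size_um = 2,
                         layer_thicknesses_um = default_layer_thicknesses(),
                         disc_width_um = 60, vessel_density = 1,
                         axis = c("superior-inferior", "nasal-temporal"),
                         exclusion_mask = NULL, seed = 1L) {
  axis <- match.arg(axis)
  check_number(width_um, "width_um", positive = TRUE)
  check_number(height_um, "height_um", positive = TRUE)
  check_number(pixel_size_um, "pixel_size_um", positive = TRUE)
  check_number(vessel_density, "vessel_density", nonneg = TRUE)
  th <- layer_thicknesses_um
  needed <- names(default_layer_thicknesses())
  if (!all(needed %in% names(th)) || any(th[needed] <= 0)) {
    stop_invalid("`layer_thicknesses_um` must name all layers with positive values.",
                 "invalid_geometry")
  }
  if (sum(th[needed]) > height_um) {
    stop_invalid("total layer thickness exceeds the phantom height.",
                 "invalid_geometry")
  }
  codes <- retina_layer_codes()
  nx <- max(1L, round(width_um / pixel_size_um))
  ny <- max(1L, round(height_um / pixel_size_um))

  # stack layers bottom-up; each at least one pixel thick
  th_px <- stats::setNames(pmax(1L, round(th[needed] / pixel_size_um)),
                           needed)
  if (sum(th_px) > ny) {
    stop_invalid("layers do not fit the phantom height at this pixel size.",
                 "invalid_geometry")
  }
  labels <- matrix(codes[["background"]], nrow = ny, ncol = nx)
  top <- ny  # fill from bottom row upward
  row_range <- list()
  for (ly in needed) {
    rows <- seq.int(top - th_px[[ly]] + 1L, top)
    labels[rows, ] <- codes[[ly]]
    row_range[[ly]] <- range(rows)
    top <- top - th_px[[ly]]
  }

  # 1-pixel hemoglobin bands at the basal (choroid-facing) and apical
  # (photoreceptor-facing) edges of the RPE
  rpe_rows <- seq.int(row_range$RPE[1], row_range$RPE[2])
  if (length(rpe_rows) >= 3) {
    labels[max(rpe_rows), ] <- codes[["rpe_basal_hb"]]
    labels[min(rpe_rows), ] <- codes[["rpe_apical_hb"]]
  }

  # optic disc: interrupts RPE..RNFL (and the RPE bands) at the centre
  disc_col <- as.integer(round(nx / 2))
  disc_half <- max(1L, round(disc_width_um / pixel_size_um / 2))
  disc_cols <- seq.int(max(1L, disc_col - disc_half),
                       min(nx, disc_col + disc_half))
  disc_rows <- seq.int(row_range$RNFL[1], row_range$RPE[2])
  labels[disc_rows, disc_cols] <- codes[["optic_disc"]]
  # disc position: centre column, inner (vitreal) retinal margin
  disc_position <- c(x = disc_col, y = row_range$RNFL[1])

  # vessels: disks of lumen pixels, seeded placement
  if (vessel_density > 0) {
    withr::local_seed(seed)
    mid <- function(r) as.integer(round(mean(r)))
    place <- function(center_row, radius_um, spacing_um) {
      n <- max(0L, round(vessel_density * width_um / spacing_um))
      if (n == 0L) return(invisible(NULL))
      cx <- sort(as.integer(ceiling(stats::runif(n, 0, nx))))
      r_px <- max(1L, round(radius_um / pixel_size_um))
      for (x0 in cx) {
        if (x0 %in% disc_cols) next
        xs <- seq.int(max(1L, x0 - r_px), min(nx, x0 + r_px))
        ys <- seq.int(max(1L, center_row - r_px), min(ny, center_row + r_px))
        for (x in xs) for (y in ys) {
          if ((x - x0)^2 + (y - center_row)^2 <= r_px^2 &&
              labels[y, x] %in% codes[c("OPL", "INL", "IPL", "GCL", "RNFL")]) {
            labels[y, x] <<- codes[["vessel_lumen"]]
          }
        }
      }
    }
    place(mid(row_range$OPL), radius_um = 4, spacing_um = 60)       # deep plexus
    place(row_range$INL[1], radius_um = 4, spacing_um = 60)         # superficial plexus (INL/IPL junction)
    place(mid(row_range$GCL), radius_um = 8, spacing_um = 300)      # retinal vessels
  }

  if (is.null(exclusion_mask)) {
    exclusion_mask <- matrix(FALSE, ny, nx)
  } else if (!is.logical(exclusion_mask) ||
             !identical(dim(exclusion_mask), dim(labels))) {
    stop_invalid("`exclusion_mask` must be a logical matrix matching the phantom.",
                 "invalid_geometry")
  }

  structure(
    list(labels = labels, pixel_size_um = pixel_size_um,
         disc_position = disc_position, exclusion_mask = exclusion_mask,
         axis = axis, legend = codes, layer_rows = row_range,
         width_um = width_um, height_um = height_um, seed = seed),
    class = "layer_label_map"
  )
}

#' @export
print.layer_label_map <- function(x, ...) {
  cat(sprintf("<layer_label_map> %d x %d px (%.3g um/px), axis %s, disc at x=%d\n",
              nrow(x$labels), ncol(x$labels), x$pixel_size_um, x$axis,
              x$disc_position[["x"]]))
  cat(sprintf("tissue codes present: %d; excluded pixels: %d\n",
              length(unique(as.vector(x$labels))), sum(x$exclusion_mask)))
  invisible(x)
}

#' Per-pixel bound-fraction ground truth
#'
#' Assigns a ground-truth bound-NAD(P)H percentage to every neural
#' retina pixel: one value for the outer retina (OS, IS, ONL), one for
#' the inner retina (OPL through RNFL), optionally with Gaussian
#' per-pixel jitter. Non-retina pixels carry the sentinel -1.
#'
#' @param map A [make_phantom()] label map.
#' @param outer_bound_pct,inner_bound_pct Ground-truth bound percentages.
#' @param jitter_sd Per-pixel Gaussian jitter SD, percentage points.
#' @param seed Seed for the jitter (required when `jitter_sd > 0`).
#' @return Numeric matrix of bound percentages with -1 outside the retina.
#' @export
layer_metabolic_profile <- function(map, outer_bound_pct = 58.9,
                                    inner_bound_pct = 60.9,
                                    jitter_sd = 0, seed = NULL) {
  stopifnot(inherits(map, "layer_label_map"))
  for (p in c(outer_bound_pct, inner_bound_pct)) {
    if (!is.finite(p) || p < 0 || p > 100) {
      stop_invalid("bound percentages must lie in [0, 100].", "invalid_argument")
    }
  }
  check_number(jitter_sd, "jitter_sd", nonneg = TRUE)
  known <- retina_layer_codes()
  if (!all(unique(as.vector(map$labels)) %in% known)) {
    stop_invalid("label map contains unknown tissue codes.",
                 "configuration_error")
  }
  reg <- region_layer_codes()
  gt <- matrix(-1, nrow(map$labels), ncol(map$labels))
  gt[map$labels %in% reg$outer] <- outer_bound_pct
  gt[map$labels %in% reg$inner] <- inner_bound_pct
  if (jitter_sd > 0) {
    if (!is.null(seed)) withr::local_seed(seed)
    idx <- which(gt >= 0)
    gt[idx] <- pmin(100, pmax(0, gt[idx] + rnorm(length(idx), 0, jitter_sd)))
  }
  gt
}
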