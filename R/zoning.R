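#' Eccentricity zone names
#' @return Character vector of the five zone names, in eccentricity
#'   order used throughout: far periphery, mid periphery, peripapillary,
#'   central, paracentral.
#' @export
zone_names <- function() {
  c("far_periphery", "mid_periphery", "peripapillary", "central",
    "paracentral")
}

#' Partition a retina section into eccentricity zones and layer regions
#'
#' Eccentricity is measured as arc length along the retina midline from
#' the optic disc (straight-line distance available as an option). Zone
#' centres sit at 200 um (peripapillary), 400 um (central) and 600 um
#' (paracentral) from the disc; the far periphery is anchored half an
#' ROI width in from the tissue end (ora serrata) so a full-width ROI
#' fits, and the mid periphery at half the disc-to-ora arc distance.
#' Both sides of the disc are labeled (superior/inferior or
#' nasal/temporal according to the section axis). Zones that do not fit
#' the tissue, or whose band would overlap an already placed zone, are
#' dropped with a warning. Regions: outer = {OS, IS, ONL}, inner =
#' {OPL, INL, IPL, GCL, RNFL}; the RPE belongs to neither.
#'
#' @param map A [make_phantom()]-style `layer_label_map` with
#'   `disc_position` set.
#' @param roi_width_um Nominal ROI width used to anchor the far
#'   periphery and to paint the zone-label bands, um.
#' @param eccentricity `"arc"` (default) or `"euclidean"`.
#' @return An object of class `zone_map`: integer `zone_labels` (0 =
#'   none, then [zone_names()] order), `region_labels` (0 none, 1 outer,
#'   2 inner), `side_labels` (0/1/2), a `centers` tibble (side, zone,
#'   arc distance, centre column) and geometry metadata.
#' @export
build_zones <- function(map, roi_width_um = 150,
                        eccentricity = c("arc", "euclidean")) {
  stopifnot(inherits(map, "layer_label_map"))
  eccentricity <- match.arg(eccentricity)
  check_number(roi_width_um, "roi_width_um", positive = TRUE)
  codes <- retina_layer_codes()
  px <- map$pixel_size_um
  labels <- map$labels
  ny <- nrow(labels); nx <- ncol(labels)
  retinal <- labels %in% codes[c("RPE", "OS", "IS", "ONL", "OPL", "INL",
                                 "IPL", "GCL", "RNFL", "vessel_lumen",
                                 "rpe_basal_hb", "rpe_apical_hb")]
  dim(retinal) <- dim(labels)
  tissue_cols <- which(colSums(retinal) > 0 |
                         colSums(matrix(labels == codes[["optic_disc"]],
                                        ny, nx)) > 0)
  if (length(tissue_cols) == 0) {
    stop_invalid("no retinal tissue found in the label map.", "invalid_input")
  }
  disc_col <- as.integer(map$disc_position[["x"]])
  if (!disc_col %in% tissue_cols) {
    stop_invalid("optic disc position lies outside the tissue.",
                 "invalid_input")
  }

  # midline y per column, interpolated over vessel/disc gaps
  midline <- rep(NA_real_, nx)
  for (cc in tissue_cols) {
    rows <- which(retinal[, cc])
    if (length(rows) > 0) midline[cc] <- mean(rows)
  }
  known <- which(!is.na(midline))
  midline[tissue_cols] <- stats::approx(known, midline[known],
                                        xout = tissue_cols, rule = 2)$y

  # arc distance from the disc centre along the midline (um)
  arc <- rep(NA_real_, nx)
  if (eccentricity == "arc") {
    seg <- sqrt(1 + c(0, diff(midline[tissue_cols]))^2) * px
    cum <- cumsum(seg) - seg[1]
    pos <- cum[match(seq_len(nx), tissue_cols)]
    arc <- abs(pos - cum[match(disc_col, tissue_cols)])
  } else {
    arc[tissue_cols] <- abs(tissue_cols - disc_col) * px
  }

  side_of <- ifelse(seq_len(nx) < disc_col, 1L,
                    ifelse(seq_len(nx) > disc_col, 2L, 0L))
  side_names <- if (map$axis == "superior-inferior") {
    c("superior", "inferior")
  } else {
    c("nasal", "temporal")
  }

  half <- roi_width_um / 2
  centers <- purrr::map_dfr(1:2, function(sd) {
    cols <- tissue_cols[side_of[tissue_cols] == sd]
    if (length(cols) == 0) return(tibble::tibble())
    ora_arc <- max(arc[cols])
    want <- tibble::tibble(
      zone = zone_names(),
      arc_um = c(ora_arc - half, ora_arc / 2, 200, 400, 600)
    )
    placed <- tibble::tibble()
    # place fixed-eccentricity zones first, then mid/far periphery
    for (i in c(3L, 4L, 5L, 2L, 1L)) {
      a <- want$arc_um[i]
      if (a - half < 0 || a + half > ora_arc + px / 2) {
        rlang::warn(sprintf("zone '%s' (%s) does not fit this section; dropped.",
                            want$zone[i], side_names[sd]))
        next
      }
      if (nrow(placed) > 0 && any(abs(placed$arc_um - a) < roi_width_um)) {
        rlang::warn(sprintf("zone '%s' (%s) overlaps another zone; dropped.",
                            want$zone[i], side_names[sd]))
        next
      }
      ctr_col <- cols[which.min(abs(arc[cols] - a))]
      placed <- dplyr::bind_rows(placed, tibble::tibble(
        side = side_names[sd], side_code = sd, zone = want$zone[i],
        arc_um = a, center_col = ctr_col))
    }
    placed
  })
  if (nrow(centers) == 0) {
    stop_invalid("no zone fits this section.", "invalid_input")
  }

  # paint per-pixel zone / region / side labels
  zone_labels <- matrix(0L, ny, nx)
  for (i in seq_len(nrow(centers))) {
    zcode <- match(centers$zone[i], zone_names())
    cols <- which(side_of == centers$side_code[i] &
                    arc >= centers$arc_um[i] - half &
                    arc < centers$arc_um[i] + half)
    zone_labels[, cols] <- zcode
  }
  reg <- region_layer_codes()
  region_labels <- matrix(0L, ny, nx)
  region_labels[labels %in% reg$outer] <- 1L
  region_labels[labels %in% reg$inner] <- 2L
  zone_labels[region_labels == 0L] <- 0L
  side_labels <- matrix(rep(side_of, each = ny), ny, nx)
  side_labels[region_labels == 0L] <- 0L

  structure(
    list(zone_labels = zone_labels, region_labels = region_labels,
         side_labels = side_labels, centers = centers,
         side_names = side_names, pixel_size_um = px,
         exclusion_mask = map$exclusion_mask,
         disc_position = map$disc_position, axis = map$axis),
    class = "zone_map"
  )
}

#' @export
print.zone_map <- function(x, ...) {
  cat(sprintf("<zone_map> %d x %d px, %d zone centres (%s axis)\n",
              nrow(x$zone_labels), ncol(x$zone_labels), nrow(x$centers),
              x$axis))
  print(x$centers)
  invisible(x)
}

#' Carve fixed-width ROIs from a zone map
#'
#' One outer-region and one inner-region ROI per (zone, side), of the
#' stated width centred on the zone centre, clipped to tissue and minus
#' the exclusion mask. Empty ROIs are dropped with a message.
#'
#' @param zones A [build_zones()] `zone_map`.
#' @param width_um ROI width, um (150 by default).
#' @return An `roi_set` tibble with columns `roi_id`, `zone`, `region`,
#'   `side`, `width_um`, and a `mask` list-column of logical matrices.
#' @export
make_rois <- function(zones, width_um = 150) {
  stopifnot(inherits(zones, "zone_map"))
  check_number(width_um, "width_um", positive = TRUE)
  px <- zones$pixel_size_um
  n_cols <- round(width_um / px)
  if (n_cols < 1) {
    stop_invalid("`width_um` is below one pixel.", "invalid_argument")
  }
  nx <- ncol(zones$zone_labels)
  rows <- purrr::pmap_dfr(
    zones$centers[, c("side", "side_code", "zone", "center_col")],
    function(side, side_code, zone, center_col) {
      cols <- seq.int(center_col - n_cols %/% 2, length.out = n_cols)
      cols <- cols[cols >= 1 & cols <= nx]
      colmask <- matrix(FALSE, nrow(zones$zone_labels), nx)
      colmask[, cols] <- TRUE
      purrr::map_dfr(c(outer = 1L, inner = 2L), function(rc) {
        m <- colmask & zones$region_labels == rc & !zones$exclusion_mask
        tibble::tibble(zone = zone, side = side,
                       region = c("outer", "inner")[rc],
                       width_um = width_um, mask = list(m),
                       n_pixels = sum(m))
      })
    })
  rows$roi_id <- paste(rows$side, rows$zone, rows$region, sep = ".")
  empty <- rows$n_pixels == 0
  if (any(empty)) {
    rlang::inform(sprintf("dropping %d empty ROI(s) after clipping: %s",
                          sum(empty),
                          paste(rows$roi_id[empty], collapse = ", ")))
    rows <- rows[!empty, ]
  }
  out <- rows[, c("roi_id", "zone", "region", "side", "width_um",
                  "n_pixels", "mask")]
  class(out) <- c("roi_set", class(out))
  out
}
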