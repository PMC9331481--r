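universal_circle_df <- function(n = 361) {
  th <- seq(0, pi, length.out = n)
  data.frame(g = 0.5 + 0.5 * cos(th), s = 0.5 * sin(th))
}

#' Phasor plot of a field
#'
#' 2-D bin counts of per-pixel (g, s) with the universal circle
#' overlaid; optionally a metabolic trajectory chord.
#'
#' @param object A `phasor_field`.
#' @param trajectory Optional [fit_trajectory()] model to overlay.
#' @param bins Number of 2-D bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phasor_field <- function(object, trajectory = NULL, bins = 150,
                                  ...) {
  sel <- object$valid & is.finite(object$g) & is.finite(object$s)
  df <- data.frame(g = object$g[sel], s = object$s[sel])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$g, y = .data$s)) +
    ggplot2::geom_bin2d(bins = bins) +
    ggplot2::geom_path(data = universal_circle_df(),
                       ggplot2::aes(x = .data$g, y = .data$s),
                       inherit.aes = FALSE, linewidth = 0.3) +
    ggplot2::scale_fill_viridis_c(trans = "log10") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 0.65)) +
    ggplot2::labs(x = "g", y = "s", fill = "pixels",
                  title = sprintf("Phasor plot (%s, harmonic %d)",
                                  object$channel, object$harmonic))
  if (!is.null(trajectory)) {
    tr <- data.frame(g = c(trajectory$free_anchor[["g"]],
                           trajectory$bound_anchor[["g"]]),
                     s = c(trajectory$free_anchor[["s"]],
                           trajectory$bound_anchor[["s"]]))
    p <- p + ggplot2::geom_line(data = tr,
                                ggplot2::aes(x = .data$g, y = .data$s),
                                inherit.aes = FALSE, colour = "red") +
      ggplot2::geom_point(data = tr,
                          ggplot2::aes(x = .data$g, y = .data$s),
                          inherit.aes = FALSE, colour = "red")
  }
  p
}

#' Tissue map of a phantom
#'
#' @param object A `layer_label_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.layer_label_map <- function(object, ...) {
  codes <- object$legend
  df <- expand.grid(y = seq_len(nrow(object$labels)),
                    x = seq_len(ncol(object$labels)))
  df$tissue <- factor(names(codes)[match(as.vector(object$labels), codes)],
                      levels = names(codes))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$tissue)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)", fill = "tissue")
}

#' Bound-fraction map
#'
#' Per-pixel bound percentage along a trajectory, rendered with the
#' conventional red (free) to blue (bound) metabolic colormap.
#'
#' @param field A calibrated `phasor_field`.
#' @param trajectory A [fit_trajectory()] model.
#' @return A ggplot object.
#' @export
plot_bound_map <- function(field, trajectory) {
  bm <- pixel_bound_map(field, trajectory)
  df <- expand.grid(y = seq_len(nrow(bm)), x = seq_len(ncol(bm)))
  df$bound <- as.vector(bm)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$bound)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "red", high = "blue",
                                 limits = c(0, 100), na.value = "black") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)", fill = "bound %")
}

#' Per-ROI bound percentages by zone and region
#'
#' @param roi_results Output of [analyze_rois()] (optionally stacked
#'   over images).
#' @return A ggplot object.
#' @export
plot_roi_results <- function(roi_results) {
  val <- if ("bound_pct" %in% names(roi_results)) "bound_pct" else "free_pct"
  ggplot2::ggplot(roi_results,
                  ggplot2::aes(x = .data$zone, y = .data[[val]],
                               colour = .data$region)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::labs(x = "eccentricity zone",
                  y = sprintf("%s NAD(P)H / FAD (%%)",
                              sub("_pct", "", val))) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Render a bound-fraction map to an RGB TIFF
#'
#' Red-to-blue colormap over [0, 100] %, black outside the tissue.
#'
#' @param field A calibrated `phasor_field`.
#' @param trajectory A [fit_trajectory()] model.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_bound_map_tiff <- function(field, trajectory, path) {
  bm <- pixel_bound_map(field, trajectory)
  f <- bm / 100
  rgb <- array(0, c(nrow(bm), ncol(bm), 3))
  rgb[, , 1] <- ifelse(is.na(f), 0, 1 - f)  # red = free
  rgb[, , 3] <- ifelse(is.na(f), 0, f)      # blue = bound
  tiff::writeTIFF(rgb, path, bits.per.sample = 8L, reduce = FALSE)
  invisible(path)
}
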