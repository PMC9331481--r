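#' Aggregate ROI bound fractions per image
#'
#' Collapses a table of per-ROI bound percentages (with an `image_id`
#' column, e.g. stacked [analyze_rois()] outputs) into per-image means:
#' over the outer and inner ROIs (zone = "all"), over each zone across
#' both regions (region = "all"), and per zone-by-region cell. Images
#' with no valid ROI are dropped with a message. Pairing per eye instead
#' of per image is available via `unit` when an `eye_id` column exists.
#'
#' @param roi_results Tibble with columns `image_id` (or `eye_id`),
#'   `zone`, `region`, `bound_pct`.
#' @param unit Aggregation unit: `"image"` (default) or `"eye"`.
#' @return Tibble: unit id, `zone`, `region`, `mean_bound_pct`, `n_rois`,
#'   where `zone`/`region` take the value `"all"` for the marginal means.
#' @export
aggregate_rois <- function(roi_results, unit = c("image", "eye")) {
  unit <- match.arg(unit)
  id_col <- if (unit == "image") "image_id" else "eye_id"
  if (!is.data.frame(roi_results) || nrow(roi_results) == 0) {
    stop_invalid("`roi_results` must be a non-empty data frame.",
                 "invalid_argument")
  }
  if (!all(c(id_col, "zone", "region", "bound_pct") %in%
           names(roi_results))) {
    stop_invalid(sprintf("`roi_results` needs columns %s, zone, region, bound_pct.",
                         id_col), "invalid_argument")
  }
  ok <- is.finite(roi_results$bound_pct)
  dropped <- setdiff(unique(roi_results[[id_col]]),
                     unique(roi_results[[id_col]][ok]))
  if (length(dropped) > 0) {
    rlang::inform(sprintf("dropping %d %s(s) with no valid ROI.",
                          length(dropped), unit))
  }
  df <- dplyr::rename(roi_results[ok, ], id = dplyr::all_of(id_col))
  summarise_cell <- function(d) {
    dplyr::summarise(d, mean_bound_pct = mean(.data$bound_pct),
                     n_rois = dplyr::n(), .groups = "drop")
  }
  by_region <- summarise_cell(dplyr::group_by(df, .data$id, .data$region))
  by_region$zone <- "all"
  by_zone <- summarise_cell(dplyr::group_by(df, .data$id, .data$zone))
  by_zone$region <- "all"
  by_cell <- summarise_cell(dplyr::group_by(df, .data$id, .data$zone,
                                            .data$region))
  out <- dplyr::bind_rows(by_region, by_zone, by_cell)
  out <- out[, c("id", "zone", "region", "mean_bound_pct", "n_rois")]
  names(out)[1] <- id_col
  out
}

#' Two-tailed paired t-test
#'
#' Paired comparison of two equal-length vectors (the pairing unit is
#' typically the image): t = mean(d) / (sd(d) / sqrt(n)) on the
#' differences d = a - b, two-tailed p from the t distribution with
#' n - 1 degrees of freedom. Degenerate zero-variance differences are
#' flagged: all-zero differences give t = 0, p = 1; constant non-zero
#' differences give p = 0 with `degenerate = TRUE`.
#'
#' @param a,b Paired numeric vectors, same length, n >= 2.
#' @param name Label for the comparison.
#' @return An object of class `paired_comparison`; see [tidy()] /
#'   [glance()] methods.
#' @export
paired_t_test <- function(a, b, name = "paired comparison") {
  if (length(a) != length(b)) {
    stop_invalid("`a` and `b` must be paired vectors of equal length.",
                 "invalid_argument")
  }
  keep <- is.finite(a) & is.finite(b)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n < 2) {
    stop_invalid("paired t-test needs at least 2 complete pairs.",
                 "invalid_argument")
  }
  d <- a - b
  degenerate <- FALSE
  if (sd(d) == 0) {
    degenerate <- TRUE
    if (mean(d) == 0) {
      t_stat <- 0; p <- 1
    } else {
      t_stat <- sign(mean(d)) * Inf; p <- 0
    }
  } else {
    tt <- stats::t.test(a, b, paired = TRUE, alternative = "two.sided")
    t_stat <- unname(tt$statistic)
    p <- tt$p.value
  }
  structure(
    list(name = name, n_pairs = n,
         mean_a = mean(a), mean_b = mean(b),
         sd_a = sd(a), sd_b = sd(b),
         sem_a = sd(a) / sqrt(n), sem_b = sd(b) / sqrt(n),
         mean_diff = mean(d), sd_diff = sd(d),
         t_stat = t_stat, df = n - 1L, p_two_tailed = p,
         degenerate = degenerate),
    class = "paired_comparison"
  )
}

#' @export
print.paired_comparison <- function(x, digits = 3, ...) {
  cat(sprintf("%s (paired, two-tailed, n = %d)\n", x$name, x$n_pairs))
  cat(sprintf("  a: %.*f +/- %.*f (SEM %.*f)   b: %.*f +/- %.*f (SEM %.*f)\n",
              digits, x$mean_a, digits, x$sd_a, digits, x$sem_a,
              digits, x$mean_b, digits, x$sd_b, digits, x$sem_b))
  p_txt <- if (x$p_two_tailed < 1e-4) "p < 0.0001" else
    sprintf("p = %.*g", digits, x$p_two_tailed)
  cat(sprintf("  t(%d) = %.*g, %s%s\n", x$df, digits, x$t_stat, p_txt,
              if (x$degenerate) " [degenerate: zero-variance differences]" else ""))
  invisible(x)
}

#' @rdname paired_t_test
#' @param x A `paired_comparison`.
#' @param ... Unused.
#' @export
tidy.paired_comparison <- function(x, ...) {
  tibble::tibble(
    name = x$name, n_pairs = x$n_pairs,
    mean_a = x$mean_a, mean_b = x$mean_b,
    sd_a = x$sd_a, sd_b = x$sd_b, sem_a = x$sem_a, sem_b = x$sem_b,
    mean_diff = x$mean_diff,
    t_stat = x$t_stat, df = x$df, p_two_tailed = x$p_two_tailed,
    degenerate = x$degenerate
  )
}

#' @rdname paired_t_test
#' @export
glance.paired_comparison <- function(x, ...) {
  tibble::tibble(n_pairs = x$n_pairs, t_stat = x$t_stat, df = x$df,
                 p_two_tailed = x$p_two_tailed, degenerate = x$degenerate)
}

#' Run the standard within-image region comparisons
#'
#' Three paired comparisons on an aggregated table from
#' [aggregate_rois()]: outer vs inner retina over all images, far
#' periphery vs central zone in the overall retina, and far periphery
#' vs central zone in the outer retina. Pairing is within image; only
#' images contributing both members of a pair enter each comparison. No
#' multiple-testing correction is applied (noted in the output).
#'
#' @param aggregated Output of [aggregate_rois()].
#' @return Tibble with one row per comparison (tidied
#'   [paired_t_test()] results plus a `correction` column, "none").
#' @export
run_region_comparisons <- function(aggregated) {
  req <- c("zone", "region", "mean_bound_pct")
  if (!is.data.frame(aggregated) || !all(req %in% names(aggregated))) {
    stop_invalid("`aggregated` must come from aggregate_rois().",
                 "invalid_argument")
  }
  id_col <- intersect(c("image_id", "eye_id"), names(aggregated))[1]
  if (is.na(id_col)) {
    stop_invalid("`aggregated` lacks an image_id/eye_id column.",
                 "invalid_argument")
  }
  pair_wide <- function(df, key, lv_a, lv_b) {
    wide <- tidyr::pivot_wider(
      df[, c(id_col, key, "mean_bound_pct")],
      names_from = dplyr::all_of(key), values_from = "mean_bound_pct")
    if (!all(c(lv_a, lv_b) %in% names(wide))) {
      stop_invalid(sprintf("aggregated table lacks '%s' and/or '%s' %s means.",
                           lv_a, lv_b, key), "missing_zone")
    }
    wide <- wide[stats::complete.cases(wide[, c(lv_a, lv_b)]), ]
    list(a = wide[[lv_a]], b = wide[[lv_b]])
  }
  reg <- pair_wide(aggregated[aggregated$zone == "all", ], "region",
                   "outer", "inner")
  zon <- pair_wide(aggregated[aggregated$region == "all", ], "zone",
                   "far_periphery", "central")
  outer_rows <- aggregated[aggregated$region == "outer" &
                             aggregated$zone != "all", ]
  zon_outer <- pair_wide(outer_rows, "zone", "far_periphery", "central")
  res <- dplyr::bind_rows(
    tidy(paired_t_test(reg$a, reg$b, "outer vs inner retina")),
    tidy(paired_t_test(zon$a, zon$b,
                       "far periphery vs central (overall retina)")),
    tidy(paired_t_test(zon_outer$a, zon_outer$b,
                       "far periphery vs central (outer retina)"))
  )
  res$correction <- "none"
  res
}
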