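#' Run the full phantom-to-statistics pipeline
#'
#' For each simulated image: phantom generation, ground-truth grids,
#' per-channel TCSPC cubes, phasor transform and calibration against a
#' same-instrument reference of known lifetime, zoning, fixed-width
#' ROIs, bound-fraction analysis (NAD(P)H; FAD when configured) and
#' phasor-position channel masks. ROI results are then aggregated per
#' image and, when at least two images were simulated, the three
#' standard paired region comparisons are run. All randomness derives
#' from the root seed, so a given (config, seed) reproduces the bundle
#' bit for bit.
#'
#' @param config A `pipeline_config` (see [default_config()],
#'   [validate_config()]); plain lists are validated first.
#' @param out_dir Optional output directory: label map, phasor fields,
#'   masks, ROI/comparison CSVs and a provenance JSON are written there.
#' @param write_cubes Also write the (large) decay cubes when `out_dir`
#'   is set.
#' @return A `retinaflim_run` bundle: `roi_results`, `aggregated`,
#'   `comparisons` (or NULL for a single image), `mask_summary`,
#'   `fields` and `masks` of the last image, the `zone` centres table,
#'   and `provenance`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         write_cubes = FALSE) {
  cfg <- validate_config(config)
  verbose <- isTRUE(cfg$verbose)
  inst <- instrument_model(cfg$instrument$repetition_period_ns,
                           cfg$instrument$n_bins,
                           cfg$instrument$irf_fwhm_ns,
                           cfg$instrument$irf_center_ns)
  omega <- angular_frequency(inst$repetition_period, cfg$analysis$harmonic)
  fluor <- default_fluorophores(
    tau_bound_nadh = cfg$truth$tau_bound_nadh_ns,
    tau_bound_fad = cfg$truth$tau_bound_fad_ns,
    tau_melanin = cfg$truth$tau_melanin_ns,
    tau_hemoglobin = cfg$truth$tau_hemoglobin_ns)
  ref_cube <- simulate_reference_cube(cfg$analysis$calibration_tau_ns, inst)
  seeds <- matrix(split_seed(cfg$seed, cfg$n_images * 8L),
                  nrow = cfg$n_images)

  roi_all <- list()
  last <- list()
  fad_rois <- NULL
  for (i in seq_len(cfg$n_images)) {
    rf_log(verbose, "image %d/%d: phantom", i, cfg$n_images)
    map <- with(cfg$phantom, make_phantom(
      width_um, height_um, pixel_size_um, disc_width_um = disc_width_um,
      vessel_density = vessel_density, axis = axis, seed = seeds[i, 1]))
    gt_nadh <- layer_metabolic_profile(map, cfg$truth$outer_bound_pct,
                                       cfg$truth$inner_bound_pct,
                                       jitter_sd = cfg$truth$jitter_sd,
                                       seed = seeds[i, 2])
    zones <- build_zones(map, cfg$analysis$roi_width_um,
                         eccentricity = cfg$analysis$eccentricity)
    rois <- make_rois(zones, cfg$analysis$roi_width_um)
    fields <- list(); masks <- list()

    simulate_field <- function(channel, gt, seed) {
      cube <- simulate_decay_cube(map, gt, fluor, inst,
                                  cfg$photons_per_pixel, channel,
                                  seed = seed)
      fld <- phasor_transform(cube, cfg$analysis$harmonic)
      fld <- calibrate_phasor(fld, ref_cube, cfg$analysis$calibration_tau_ns)
      if (cfg$analysis$median_filter_window > 1L) {
        fld <- median_filter_phasor(fld, cfg$analysis$median_filter_window)
      }
      list(cube = cube, field = fld)
    }

    rf_log(verbose, "image %d: NAD(P)H channel", i)
    nadh <- simulate_field("nadh", gt_nadh, seeds[i, 3])
    fields$nadh <- nadh$field
    res <- analyze_rois(nadh$field, rois, cfg$analysis$free_tau_nadh_ns,
                        global_trajectory = cfg$analysis$global_trajectory)
    res$image_id <- i
    res$channel <- "nadh"
    roi_all[[length(roi_all) + 1L]] <- res

    if ("fad" %in% cfg$channels) {
      rf_log(verbose, "image %d: FAD channel", i)
      gt_fad <- layer_metabolic_profile(map, 100 - cfg$truth$fad_free_pct,
                                        100 - cfg$truth$fad_free_pct,
                                        jitter_sd = cfg$truth$jitter_sd,
                                        seed = seeds[i, 4])
      fad <- simulate_field("fad", gt_fad, seeds[i, 5])
      fields$fad <- fad$field
      res_fad <- analyze_rois(fad$field, rois, cfg$analysis$free_tau_fad_ns,
                              global_trajectory = cfg$analysis$global_trajectory,
                              report = "free")
      res_fad$image_id <- i
      res_fad$channel <- "fad"
      fad_rois <- res_fad
    }
    if ("hb_melanin" %in% cfg$channels) {
      rf_log(verbose, "image %d: Hb/melanin channel", i)
      hb <- simulate_field("hb_melanin", NULL, seeds[i, 6])
      fields$hb_melanin <- hb$field
      r <- cfg$analysis$selector_radius
      fl <- cfg$analysis$intensity_floor
      masks$melanin <- phasor_select(
        hb$field, selector_from_spec(fluor$melanin, omega, r,
                                     intensity_floor = fl))
      masks$hemoglobin <- phasor_select(
        hb$field, selector_from_spec(fluor$hemoglobin, omega, r,
                                     intensity_floor = fl))
    }
    if ("shg" %in% cfg$channels) {
      rf_log(verbose, "image %d: SHG channel", i)
      shg <- simulate_field("shg", NULL, seeds[i, 7])
      fields$shg <- shg$field
      masks$shg <- shg_mask(shg$field, cfg$analysis$selector_radius,
                            cfg$analysis$intensity_floor)
    }
    last <- list(map = map, zones = zones, rois = rois, fields = fields,
                 masks = masks)
    if (!is.null(out_dir) && isTRUE(write_cubes)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_decay_cube(nadh$cube,
                       file.path(out_dir, sprintf("image%03d_nadh.tif", i)))
    }
  }

  roi_results <- dplyr::bind_rows(roi_all)
  aggregated <- aggregate_rois(roi_results, unit = cfg$stats$pairing)
  comparisons <- NULL
  if (cfg$n_images >= 2) {
    comparisons <- tryCatch(run_region_comparisons(aggregated),
                            retinaflim_error = function(e) {
                              rlang::warn(paste("comparisons skipped:",
                                                conditionMessage(e)))
                              NULL
                            })
  }
  mask_summary <- purrr::imap_dfr(last$masks, function(m, nm) {
    tibble::tibble(mask = nm, n_pixels = sum(m))
  })
  provenance <- list(config_hash = config_hash(cfg), seed = cfg$seed,
                     n_images = cfg$n_images,
                     package_version = as.character(
                       utils::packageVersion("retinaflim")),
                     r_version = paste(R.version$major, R.version$minor,
                                       sep = "."))
  bundle <- structure(
    list(config = cfg, roi_results = roi_results, aggregated = aggregated,
         comparisons = comparisons, mask_summary = mask_summary,
         map = last$map, zones = last$zones, rois = last$rois,
         fields = last$fields, masks = last$masks,
         fad_rois = fad_rois, provenance = provenance),
    class = "retinaflim_run")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_label_map(last$map, file.path(out_dir, "label_map.tif"))
    for (nm in names(last$fields)) {
      write_phasor_field(last$fields[[nm]],
                         file.path(out_dir, paste0("phasor_", nm, ".tif")))
    }
    for (nm in names(last$masks)) {
      write_mask(last$masks[[nm]],
                 file.path(out_dir, paste0("mask_", nm, ".tif")))
    }
    utils::write.csv(roi_results, file.path(out_dir, "roi_results.csv"),
                     row.names = FALSE)
    utils::write.csv(aggregated, file.path(out_dir, "aggregated.csv"),
                     row.names = FALSE)
    if (!is.null(comparisons)) {
      utils::write.csv(comparisons, file.path(out_dir, "comparisons.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
    write_config(cfg, file.path(out_dir, "config.yaml"))
  }
  bundle
}

#' @export
print.retinaflim_run <- function(x, ...) {
  cat(sprintf("<retinaflim_run> %d image(s), %d ROI result(s)\n",
              x$config$n_images, nrow(x$roi_results)))
  if (!is.null(x$comparisons)) {
    cat("comparisons:\n")
    print(x$comparisons[, c("name", "n_pairs", "mean_a", "mean_b",
                            "p_two_tailed")])
  }
  invisible(x)
}
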