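test_that("phantom contains all tissue classes in anatomical order", {
  map <- make_phantom(width_um = 600, height_um = 300, pixel_size_um = 1,
                      seed = 7)
  codes <- retina_layer_codes()
  present <- unique(as.vector(map$labels))
  expect_gte(length(present), 14)
  # every class is present in the default phantom
  expect_true(all(codes %in% present))
  # scan columns: the apical RPE band (RPE edge) is adjacent to the OS band
  col <- map$labels[, 10]
  apical <- which(col == codes[["rpe_apical_hb"]])
  expect_true(all(col[apical - 1] == codes[["OS"]]))
  # layers ordered RPE -> RNFL along the inner-retina (decreasing y) axis
  order_expected <- codes[c("RPE", "OS", "IS", "ONL", "OPL", "INL", "IPL",
                            "GCL", "RNFL")]
  rows_of <- vapply(order_expected, function(cd) mean(which(col == cd)),
                    numeric(1))
  rows_of[["RPE"]] <- mean(which(col %in% codes[c("RPE", "rpe_basal_hb",
                                                  "rpe_apical_hb")]))
  expect_true(all(diff(rows_of) < 0))
  # disc inside tissue, on the inner margin
  expect_true(map$labels[map$disc_position[["y"]],
                         map$disc_position[["x"]]] == codes[["optic_disc"]])
})

test_that("vessel density zero removes all vessel lumen pixels", {
  map <- make_phantom(width_um = 400, height_um = 300, pixel_size_um = 2,
                      vessel_density = 0, seed = 3)
  expect_equal(sum(map$labels == retina_layer_codes()[["vessel_lumen"]]), 0)
})

test_that("phantom generation is seed-deterministic", {
  m1 <- make_phantom(width_um = 400, height_um = 300, seed = 11)
  m2 <- make_phantom(width_um = 400, height_um = 300, seed = 11)
  m3 <- make_phantom(width_um = 400, height_um = 300, seed = 12)
  expect_identical(m1$labels, m2$labels)
  expect_false(identical(m1$labels, m3$labels))
})

test_that("invalid phantom geometry is rejected", {
  expect_error(make_phantom(width_um = -5), class = "invalid_argument")
  expect_error(make_phantom(height_um = 0), class = "invalid_argument")
  expect_error(make_phantom(height_um = 100,
                            layer_thicknesses_um = default_layer_thicknesses()),
               class = "invalid_geometry")
})

test_that("metabolic ground truth assigns region values exactly", {
  map <- small_phantom()
  codes <- retina_layer_codes()
  gt <- layer_metabolic_profile(map, 58.9, 60.9, jitter_sd = 0)
  expect_true(all(gt[map$labels == codes[["ONL"]]] == 58.9))
  expect_true(all(gt[map$labels == codes[["OS"]]] == 58.9))
  expect_true(all(gt[map$labels == codes[["IPL"]]] == 60.9))
  # sentinel outside the retina
  expect_true(all(gt[map$labels == codes[["sclera"]]] == -1))
  expect_true(all(gt[map$labels == codes[["RPE"]]] == -1))
  # null configuration: uniform 50 across all retina pixels
  gt50 <- layer_metabolic_profile(map, 50, 50, jitter_sd = 0)
  reg <- region_layer_codes()
  expect_true(all(gt50[map$labels %in% c(reg$outer, reg$inner)] == 50))
  expect_error(layer_metabolic_profile(map, -2, 50),
               class = "invalid_argument")
})

test_that("ground-truth jitter preserves the per-layer mean", {
  map <- small_phantom()
  gt <- layer_metabolic_profile(map, 58.9, 60.9, jitter_sd = 2, seed = 5)
  onl <- gt[map$labels == retina_layer_codes()[["ONL"]]]
  sem <- 2 / sqrt(length(onl))
  expect_lt(abs(mean(onl) - 58.9), 3 * sem)
})

test_that("simulated decay tail recovers the lifetime (log-linear oracle)", {
  inst <- std_instrument()
  cube <- mono_cube(0.4, photons = 1e6, n_pixels = 1)
  y <- cube$counts[1, 1, ]
  t <- cube$time_axis
  # fit the pure tail, away from the IRF and from the wrap-around
  sel <- t > inst$irf_center + 5 * inst$irf_fwhm & t < 8 & y > 0
  fit <- stats::lm(log(y[sel]) ~ t[sel])
  tau_hat <- -1 / unname(stats::coef(fit)[2])
  expect_lt(abs(tau_hat - 0.4) / 0.4, 0.02)
})

test_that("decay simulation rejects a non-positive photon budget", {
  map <- small_phantom()
  gt <- layer_metabolic_profile(map)
  expect_error(simulate_decay_cube(map, gt, photons_per_pixel = 0),
               class = "invalid_argument")
})

test_that("total counts follow the Poisson photon budget", {
  inst <- std_instrument()
  # 50/50 mixture of tau 0.4 and 3.2 at 1e6 photons in one pixel
  map <- structure(list(labels = matrix(retina_layer_codes()[["ONL"]], 1, 1),
                        pixel_size_um = 1,
                        disc_position = c(x = 1, y = 1),
                        exclusion_mask = matrix(FALSE, 1, 1),
                        axis = "superior-inferior",
                        legend = retina_layer_codes()),
                   class = "layer_label_map")
  gt <- matrix(50, 1, 1)
  cube <- simulate_decay_cube(map, gt, photons_per_pixel = 1e6, seed = 2)
  expect_lt(abs(sum(cube$counts) - 1e6), 3 * sqrt(1e6))
  # photon conservation in expectation across many pixels
  mp <- small_phantom()
  gtp <- layer_metabolic_profile(mp)
  c2 <- simulate_decay_cube(mp, gtp, photons_per_pixel = 200, seed = 4)
  per_pixel <- apply(c2$counts, c(1, 2), sum)
  emitting <- per_pixel[gtp >= 0]
  expect_gt(length(emitting), 100)
  expect_lt(abs(mean(emitting) - 200),
            3 * sqrt(200 / length(emitting)))
})

test_that("decay cubes are bit-identical under a fixed seed", {
  map <- small_phantom()
  gt <- layer_metabolic_profile(map)
  c1 <- simulate_decay_cube(map, gt, photons_per_pixel = 100, seed = 9)
  c2 <- simulate_decay_cube(map, gt, photons_per_pixel = 100, seed = 9)
  expect_identical(c1$counts, c2$counts)
})

test_that("fluorophore specs enforce their invariants", {
  expect_error(fluorophore_spec("x", c(-1), channel = "nadh"),
               class = "invalid_argument")
  expect_error(fluorophore_spec("x", c(1, 2), c(0.7, 0.7), channel = "nadh"),
               class = "invalid_argument")
  expect_error(fluorophore_spec("x", 1, channel = "shg",
                                instantaneous = TRUE),
               class = "invalid_argument")
  sp <- fluorophore_spec("x", c(0.5, 2), c(0.25, 0.75), channel = "fad")
  expect_equal(sum(sp$fractions), 1)
})

test_that("unknown channels and missing ground truth are configuration errors", {
  map <- small_phantom()
  expect_error(simulate_decay_cube(map, NULL, channel = "uv"),
               class = "configuration_error")
  expect_error(simulate_decay_cube(map, NULL, channel = "nadh"),
               class = "configuration_error")
})

test_that("region-mean generator hits its nominal moments", {
  sim <- simulate_region_means(n_images = 4000, seed = 8)
  expect_lt(abs(mean(sim$outer) - 58.9), 0.2)
  expect_lt(abs(mean(sim$inner) - 60.9), 0.15)
  expect_lt(abs(sd(sim$outer) - 3.7), 0.15)
  expect_lt(abs(sd(sim$inner) - 2.6), 0.15)
  expect_error(simulate_region_means(image_effect_sd = 3),
               class = "invalid_argument")
})
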