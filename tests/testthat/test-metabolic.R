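test_that("trajectory geometry solves the line-circle intersection", {
  omega <- std_omega()
  # tau = 0 anchor (1, 0) through the circle centre: diameter chord to (0, 0)
  tr <- fit_trajectory(c(0.5, 0), free_tau = 0, omega = omega)
  expect_equal(unname(tr$bound_anchor), c(0, 0), tolerance = 1e-12)
  expect_equal(tr$chord_length, 1)
  # com already on the circle: the bound anchor is the com itself
  p <- lifetime_to_phasor(3.2, omega)
  tr2 <- fit_trajectory(c(p$g, p$s), free_tau = 0.4, omega = omega)
  expect_equal(unname(tr2$bound_anchor), c(p$g, p$s), tolerance = 1e-9)
  # general case against an independent quadratic-root oracle
  com <- c(0.7, 0.3)
  tr3 <- fit_trajectory(com, free_tau = 0.4, omega = omega)
  A <- unname(tr3$free_anchor)
  d <- com - A
  # roots of |A + t d - c|^2 = 1/4 via the quadratic formula
  a2 <- sum(d^2); b2 <- 2 * sum((A - c(0.5, 0)) * d)
  c2 <- sum((A - c(0.5, 0))^2) - 0.25
  roots <- (-b2 + c(-1, 1) * sqrt(b2^2 - 4 * a2 * c2)) / (2 * a2)
  t_other <- roots[which.max(abs(roots))]
  expect_equal(unname(tr3$bound_anchor), A + t_other * d, tolerance = 1e-12)
  # both anchors satisfy the circle equation to 1e-9
  for (anch in list(tr3$free_anchor, tr3$bound_anchor)) {
    expect_lt(abs((anch[["g"]] - 0.5)^2 + anch[["s"]]^2 - 0.25), 1e-9)
  }
})

test_that("degenerate and out-of-circle centres of mass are handled", {
  omega <- std_omega()
  fa <- lifetime_to_phasor(0.4, omega)
  expect_error(fit_trajectory(c(fa$g, fa$s), 0.4, omega),
               class = "degenerate_trajectory")
  expect_warning(tr <- fit_trajectory(c(1.2, 0.3), 0.4, omega),
                 "clamped")
  expect_lt(abs((tr$bound_anchor[["g"]] - 0.5)^2 +
                  tr$bound_anchor[["s"]]^2 - 0.25), 1e-9)
})

test_that("bound fraction is exact at the endpoints and linear between them", {
  omega <- std_omega()
  tr <- fit_trajectory(c(0.7, 0.3), free_tau = 0.4, omega = omega)
  expect_identical(bound_fraction(tr, tr$free_anchor), 0)
  expect_identical(bound_fraction(tr, tr$bound_anchor), 100)
  A <- tr$free_anchor; B <- tr$bound_anchor
  expect_equal(bound_fraction(tr, (A + B) / 2), 50, tolerance = 1e-12)
  for (f in c(0.1, 0.25, 0.589, 0.997)) {
    mix <- (1 - f) * A + f * B
    expect_equal(bound_fraction(tr, mix), 100 * f, tolerance = 1e-6)
  }
  # clamped to [0, 100] beyond the anchors
  expect_equal(bound_fraction(tr, A - 0.05 * (B - A)), 0)
  expect_equal(bound_fraction(tr, B + 0.05 * (B - A)), 100)
})

test_that("FAD trajectories report the free percentage convention", {
  omega <- std_omega()
  com <- c(0.35, 0.4)
  tr <- fit_trajectory(com, free_tau = 2.6, omega = omega)
  expect_equal(fad_free_fraction(tr, tr$free_anchor), 100)
  expect_equal(fad_free_fraction(tr, tr$bound_anchor), 0)
  expect_equal(fad_free_fraction(tr, com) + bound_fraction(tr, com), 100)
})

test_that("a noiseless ROI at ground truth 58.9% is recovered within 1 pp", {
  inst <- std_instrument()
  # mixture pixel built from the forward model at 1e5 photons + Poisson
  sh <- (1 - 0.589) * decay_shape(0.4, inst) + 0.589 * decay_shape(3.2, inst)
  n_px <- 75 * 40  # a 150 um x 80 um ROI at 2 um pixels
  withr::with_seed(21, {
    cts <- matrix(rpois(n_px * inst$n_bins,
                        rep(sh * 1e5, each = n_px)), n_px, inst$n_bins)
  })
  cube <- raw_cube(array(cts, c(1, n_px, inst$n_bins)), inst$time_axis)
  f <- calibrate_phasor(phasor_transform(cube), std_reference(), 1.0)
  com <- phasor_center_of_mass(f)
  tr <- fit_trajectory(com, 0.4, f$omega)
  expect_lt(abs(bound_fraction(tr, com) - 58.9), 1.0)
  # FAD convention: ground truth 75.3% free
  shf <- 0.753 * decay_shape(2.6, inst) + (1 - 0.753) * decay_shape(0.3, inst)
  withr::with_seed(22, {
    ctsf <- matrix(rpois(n_px * inst$n_bins,
                         rep(shf * 1e5, each = n_px)), n_px, inst$n_bins)
  })
  cubef <- raw_cube(array(ctsf, c(1, n_px, inst$n_bins)), inst$time_axis)
  ff <- calibrate_phasor(phasor_transform(cubef), std_reference(), 1.0)
  comf <- phasor_center_of_mass(ff)
  trf <- fit_trajectory(comf, 2.6, ff$omega)
  expect_lt(abs(fad_free_fraction(trf, comf) - 75.3), 1.0)
})

test_that("analyze_rois recovers ROI bound fractions and handles masks", {
  map <- small_phantom()
  gt <- layer_metabolic_profile(map, 58.9, 60.9)
  cube <- simulate_decay_cube(map, gt, photons_per_pixel = 2e4, seed = 13)
  f <- calibrate_phasor(phasor_transform(cube), std_reference(), 1.0)
  rois <- suppressWarnings(make_rois(build_zones(map)))
  res <- analyze_rois(f, rois, free_tau = 0.4)
  expect_true(all(c("roi_id", "zone", "region", "bound_pct") %in% names(res)))
  # ordering preserved: inner ground truth above outer
  expect_gt(mean(res$bound_pct[res$region == "inner"]),
            mean(res$bound_pct[res$region == "outer"]))
  # a pure-free ROI reports 0% bound
  inst <- std_instrument()
  free_cts <- matrix(decay_shape(0.4, inst) * 1e6, 20, inst$n_bins,
                     byrow = TRUE)
  free_cube <- raw_cube(array(free_cts, c(2, 10, inst$n_bins)),
                        inst$time_axis)
  ffree <- calibrate_phasor(phasor_transform(free_cube), std_reference(), 1.0)
  roi1 <- tibble::tibble(roi_id = "r1", zone = "central", region = "outer",
                         side = "superior", width_um = 150,
                         n_pixels = 20L,
                         mask = list(matrix(TRUE, 2, 10)))
  class(roi1) <- c("roi_set", class(roi1))
  r1 <- analyze_rois(ffree, roi1, free_tau = 0.4)
  expect_lt(r1$bound_pct, 1e-6)
})

test_that("exclusion masks restrict the centre of mass to unmasked pixels", {
  map <- small_phantom()
  gt <- layer_metabolic_profile(map, 58.9, 60.9)
  cube <- simulate_decay_cube(map, gt, photons_per_pixel = 5e3, seed = 14)
  f <- calibrate_phasor(phasor_transform(cube), std_reference(), 1.0)
  rois <- suppressWarnings(make_rois(build_zones(map)))
  roi <- rois[1, ]
  # exclude the left half of the ROI's own columns
  roi_cols <- sort(unique(which(roi$mask[[1]], arr.ind = TRUE)[, 2]))
  excl <- matrix(FALSE, nrow(map$labels), ncol(map$labels))
  excl[, roi_cols[seq_len(length(roi_cols) %/% 2)]] <- TRUE
  res <- analyze_rois(f, roi, 0.4, exclusion_mask = excl)
  manual <- phasor_center_of_mass(f, roi$mask[[1]] & !excl)
  expect_equal(res$g_com, manual$g, tolerance = 1e-12)
  expect_equal(res$n_pixels, manual$n_pixels)
  # fully excluded -> empty-result error
  all_excl <- matrix(TRUE, nrow(map$labels), ncol(map$labels))
  expect_error(analyze_rois(f, roi, 0.4, exclusion_mask = all_excl),
               class = "empty_result")
})

test_that("recovery error shrinks monotonically with the photon budget", {
  map <- small_phantom()
  mae <- sapply(c(1e3, 1e4, 1e5), function(ph) {
    errs <- sapply(1:4, function(s) {
      rec <- recover_regions(map, photons = ph, seed = 100 + s)
      mean(abs(rec - c(58.9, 60.9)))
    })
    mean(errs)
  })
  expect_true(all(diff(mae) < 0))
  expect_lt(mae[3], 1.0)
})
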