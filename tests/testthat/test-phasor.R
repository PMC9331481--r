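test_that("phasor transform reproduces the degenerate closed forms", {
  inst <- std_instrument()
  N <- inst$n_bins
  t0_axis <- (seq_len(N) - 1) * inst$bin_width  # axis starting at t = 0
  # all counts in the t = 0 bin: an instantaneous pulse sits at (1, 0)
  delta <- matrix(0, 1, N); delta[1, 1] <- 1000
  f <- phasor_transform(raw_cube(delta, t0_axis))
  expect_equal(f$g[1, 1], 1, tolerance = 1e-12)
  expect_equal(f$s[1, 1], 0, tolerance = 1e-12)
  # uniform counts over a full period integrate the sinusoids to zero
  unif <- matrix(10, 1, N)
  fu <- phasor_transform(raw_cube(unif, inst$time_axis))
  expect_equal(fu$g[1, 1], 0, tolerance = 1e-12)
  expect_equal(fu$s[1, 1], 0, tolerance = 1e-12)
})

test_that("calibrated noiseless tau = 0.4 ns lands at the closed form", {
  f <- calibrated_field(mono_cube(0.4))
  cf <- lifetime_to_phasor(0.4, std_omega())
  expect_equal(f$g[1, 1], cf$g, tolerance = 1e-6)
  expect_equal(f$s[1, 1], cf$s, tolerance = 1e-6)
  # numeric anchor from the closed form at omega = 2 pi / 12.5
  expect_equal(cf$g, 0.96115, tolerance = 1e-4)
  expect_equal(cf$s, 0.19326, tolerance = 1e-4)
})

test_that("transform flags empty input and zero-intensity pixels", {
  inst <- std_instrument()
  zeros <- matrix(0, 2, inst$n_bins)
  expect_error(phasor_transform(raw_cube(zeros, inst$time_axis)),
               class = "invalid_input")
  mixed <- array(0, c(1, 2, inst$n_bins)); mixed[1, 1, ] <- 5
  f <- phasor_transform(raw_cube(mixed, inst$time_axis))
  expect_true(f$valid[1, 1])
  expect_false(f$valid[1, 2])
  expect_true(is.na(f$g[1, 2]))
})

test_that("lifetime_to_phasor obeys the universal-circle closed form", {
  omega <- std_omega()
  p0 <- lifetime_to_phasor(0, omega)
  expect_equal(c(p0$g, p0$s), c(1, 0))
  # omega * tau = 1 forces (0.5, 0.5)
  p1 <- lifetime_to_phasor(1 / omega, omega)
  expect_equal(c(p1$g, p1$s), c(0.5, 0.5))
  p26 <- lifetime_to_phasor(2.6, omega)
  expect_equal((p26$g - 0.5)^2 + p26$s^2, 0.25, tolerance = 1e-12)
  expect_gt(p26$s, 0)
  expect_error(lifetime_to_phasor(-1, omega), class = "invalid_argument")
})

test_that("self-calibration is an identity and tau = 0 references map to (1,0)", {
  inst <- std_instrument()
  cube <- mono_cube(2.6)
  f <- calibrate_phasor(phasor_transform(cube), cube, 2.6)
  cf <- lifetime_to_phasor(2.6, std_omega())
  expect_equal(f$g[1, 1], cf$g, tolerance = 0.005)
  expect_equal(f$s[1, 1], cf$s, tolerance = 0.005)
  # near-ideal instrument: calibration factor close to identity
  ideal <- instrument_model(irf_fwhm = 1e-4, irf_center = 1e-6)
  cube_i <- simulate_reference_cube(1.0, ideal)
  f_i <- calibrate_phasor(phasor_transform(cube_i), cube_i, 1.0)
  expect_equal(Mod(f_i$calibration$factor), 1, tolerance = 0.01)
  expect_equal(Arg(f_i$calibration$factor), 0, tolerance = 0.05)
  # an instantaneous (SHG-like) reference calibrates to the zero-lifetime point
  shg_ref <- raw_cube(matrix(decay_shape(NULL, inst, instantaneous = TRUE) * 1e5,
                             1, inst$n_bins, byrow = TRUE), inst$time_axis)
  f_s <- calibrate_phasor(phasor_transform(shg_ref), shg_ref, 0)
  expect_equal(f_s$g[1, 1], 1, tolerance = 1e-9)
  expect_equal(f_s$s[1, 1], 0, tolerance = 1e-9)
  expect_error(calibrate_phasor(f, raw_cube(matrix(0, 1, inst$n_bins),
                                            inst$time_axis), 1),
               class = "invalid_input")
})

test_that("calibrated mono-exponential phasors lie on the universal circle", {
  inst <- std_instrument()
  for (h in c(1L, 2L, 3L)) {
    ref <- phasor_transform(simulate_reference_cube(1.0, inst), h)
    for (tau in c(0.05, 0.4, 1.7, 2.6, 3.2, 6)) {
      f <- calibrate_phasor(phasor_transform(mono_cube(tau), h), ref, 1.0)
      resid <- abs((f$g[1, 1] - 0.5)^2 + f$s[1, 1]^2 - 0.25)
      expect_lt(resid, 1e-6)
      # harmonic consistency: s/g = n * omega * tau
      expect_equal(f$s[1, 1] / f$g[1, 1], std_omega(h) * tau,
                   tolerance = 1e-6)
    }
  }
})

test_that("phasor mixtures combine linearly by fractional intensity", {
  inst <- std_instrument()
  sh1 <- decay_shape(0.4, inst)
  sh2 <- decay_shape(3.2, inst)
  omega <- std_omega()
  ref <- std_reference()
  for (fbound in c(0.2, 0.589, 0.8)) {
    mix <- (1 - fbound) * sh1 + fbound * sh2
    cube <- raw_cube(matrix(mix * 1e6, 1, inst$n_bins, byrow = TRUE),
                     inst$time_axis)
    f <- calibrate_phasor(phasor_transform(cube), ref, 1.0)
    p <- lifetime_to_phasor(c(0.4, 3.2), omega)
    expect_equal(f$g[1, 1], (1 - fbound) * p$g[1] + fbound * p$g[2],
                 tolerance = 1e-9)
    expect_equal(f$s[1, 1], (1 - fbound) * p$s[1] + fbound * p$s[2],
                 tolerance = 1e-9)
  }
})

test_that("tau ordering is monotone along the circle", {
  taus <- c(0.1, 0.4, 1, 2.6, 3.2, 8)
  p <- lifetime_to_phasor(taus, std_omega())
  expect_true(all(diff(p$g) < 0))  # from (1,0) toward (0,0)
  ang <- atan2(p$s, p$g - 0.5)
  expect_true(all(diff(ang) > 0))
})

test_that("centre of mass weighting follows photon counts", {
  inst <- std_instrument()
  N <- inst$n_bins
  cts <- array(0, c(1, 2, N))
  cts[1, 1, 1] <- 1     # 1 photon at t = 0: phasor (1, 0)
  cts[1, 2, ] <- 3 / N  # 3 photons spread uniformly: phasor (0, 0)
  f <- phasor_transform(raw_cube(cts, (seq_len(N) - 1) * inst$bin_width))
  # single-pixel mask returns that pixel's phasor
  m1 <- matrix(c(TRUE, FALSE), 1, 2)
  com1 <- phasor_center_of_mass(f, m1)
  expect_equal(com1$g, f$g[1, 1])
  # intensities 1 and 3 at (1,0) and (0,0): weighted mean (0.25, 0)
  com <- phasor_center_of_mass(f)
  expect_equal(com$g, 0.25, tolerance = 1e-9)
  expect_equal(com$s, 0, tolerance = 1e-9)
  # unweighted option: midpoint
  comu <- phasor_center_of_mass(f, weighted = FALSE)
  expect_equal(comu$g, 0.5, tolerance = 1e-9)
  expect_error(phasor_center_of_mass(f, matrix(FALSE, 1, 2)),
               class = "empty_mask")
})

test_that("median filter removes salt noise and respects its contract", {
  inst <- std_instrument()
  cts <- array(0, c(3, 3, inst$n_bins))
  cts[, , 1] <- 100
  f <- phasor_transform(raw_cube(cts, (seq_len(inst$n_bins) - 1) *
                                   inst$bin_width))
  expect_error(median_filter_phasor(f, 2), class = "invalid_argument")
  expect_identical(median_filter_phasor(f, 1), f)
  # constant field unchanged
  ff <- median_filter_phasor(f, 3)
  expect_equal(ff$g, f$g, tolerance = 1e-12)
  # a single outlier in a flat field is removed
  f2 <- f
  f2$g[2, 2] <- -5
  f3 <- median_filter_phasor(f2, 3)
  expect_equal(f3$g[2, 2], f$g[1, 1], tolerance = 1e-12)
})
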