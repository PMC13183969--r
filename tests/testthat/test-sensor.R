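test_that("expected_electrons matches the photometric relation and is linear in power", {
  sp <- sensor_spec()
  expect_equal(expected_electrons(0, 695, sp), 0)

  # independent hand evaluation of P*t*eta*lambda/(h*c) at 1 pW, 695 nm
  h <- 6.62607015e-34; cc <- 2.99792458e8
  hand <- 1e-12 * 0.025 * 0.8406 * 695e-9 / (h * cc)
  expect_equal(expected_electrons(1e-12, 695, sp, n_pixels = 1), hand,
               tolerance = 1e-12)

  p <- 10^runif(5, -12, -6)
  expect_equal(expected_electrons(2 * p, 830, sp, 7),
               2 * expected_electrons(p, 830, sp, 7))
  expect_error(expected_electrons(1e-9, 550, sp), "quantum")
})

test_that("sample_adu reproduces the Poisson/Gaussian/clip model", {
  q0 <- sensor_spec(read_noise_e = 0)
  expect_true(all(sample_adu(0, q0, n = 1000) == 0))

  sp <- sensor_spec()
  set.seed(5)
  x <- sample_adu(1000, sp, n = 1e5)
  expect_equal(mean(x), 1000 / 2.33, tolerance = 2e-3)  # 429.18 ADU
  expect_true(all(sample_adu(1e8, sp, n = 100) == 4095))

  # bounds hold for any flux
  for (mu in c(0, 1, 1e3, 1e6, 1e9)) {
    v <- sample_adu(mu, sp, n = 500)
    expect_true(all(v >= 0 & v <= 4095))
  }
})

test_that("photon-transfer statistics match the analytic noise model", {
  # zero flux: ADU variance ~ (Q/CG)^2 (quantization disabled for the
  # clean comparison; clipping is avoided via pedestal)
  sp <- sensor_spec(offset_adu = 500, quantize = FALSE)
  set.seed(7)
  dark <- sample_adu(0, sp, n = 2e5)
  expect_equal(var(dark), (3.57 / 2.33)^2, tolerance = 0.03)

  # high flux: summed-electron variance ~ mean (shot-noise limited)
  sp2 <- sensor_spec(quantize = FALSE)
  bright <- sample_adu(5000, sp2, n = 5e4)
  e <- bright * 2.33
  expect_equal(var(e), 5000 + 3.57^2, tolerance = 0.05)
})

test_that("aggregated ROI sampling agrees with per-pixel rendering", {
  sp <- tiny_sensor()
  lay <- spot_layout(1, sp, radius_px = 5)
  n_px <- roi_pixel_count(5)
  mu <- 800  # electrons/pixel
  pw <- mu / expected_electrons(1, 695, sp, n_px)
  set.seed(11)
  per_pixel <- replicate(400, {
    fr <- render_frame(lay, data.frame(detector_id = 1, wavelength_nm = 695,
                                       power_w = pw), sp)
    mean_gray_value(fr, roi_spec(lay$cx[1], lay$cy[1], 5))
  })
  agg <- roi_mgv_sample(mu, n_px, sp, n = 400)
  expect_equal(mean(per_pixel), mean(agg), tolerance = 5e-3)
  expect_equal(sd(per_pixel), sd(agg), tolerance = 0.25)
})

test_that("MGV responds linearly to power until saturation", {
  sp <- noiseless_sensor()
  n_px <- roi_pixel_count(5)
  gain <- expected_electrons(1, 695, sp, n_px) / sp$conversion_gain
  p_sat <- 4095 / gain
  p <- seq(0.05, 0.9, by = 0.05) * p_sat
  mgv <- vapply(p, function(pp)
    roi_mgv_sample(expected_electrons(pp, 695, sp, n_px), n_px, sp), 0)
  fit <- suppressWarnings(linear_fit_r2(p, mgv))  # perfect fit warning
  expect_gt(fit$r_squared, 1 - 1e-12)
  # beyond saturation the value pins to the ceiling
  expect_equal(unname(roi_mgv_sample(expected_electrons(2 * p_sat, 695, sp, n_px),
                                     n_px, sp)), 4095)
})

test_that("frame rendering fills spot discs and leaves noise-only elsewhere", {
  sp <- tiny_sensor(read_noise_e = 0)
  lay <- spot_layout(1, sp, radius_px = 5)
  fr0 <- render_frame(lay, data.frame(detector_id = 1, wavelength_nm = 695,
                                      power_w = 0), sp, full = TRUE)
  expect_true(all(fr0$adu == 0))

  expect_equal(roi_pixel_count(102), 32681)
  expect_equal(roi_pixel_count(102), pi * 102^2, tolerance = 2e-4)

  # uniform flux of 233 e-/px -> MGV ~ 100 ADU
  sp2 <- tiny_sensor()
  n_px <- roi_pixel_count(5)
  pw <- 233 / expected_electrons(1, 695, sp2, n_px)
  set.seed(3)
  mgv <- mean(replicate(50, {
    fr <- render_frame(lay, data.frame(detector_id = 1, wavelength_nm = 695,
                                       power_w = pw), sp2)
    mean_gray_value(fr, roi_spec(lay$cx[1], lay$cy[1], 5))
  }))
  expect_equal(mgv, 100, tolerance = 0.01)
})

test_that("spot layouts reject overlap and out-of-bounds placements", {
  sp <- tiny_sensor()
  expect_error(spot_layout(4, sp, radius_px = 20), "overlap|bounds")
  lay <- spot_layout(16, sensor_spec(), radius_px = 102)
  expect_equal(nrow(lay), 32L)
  # the two wavelength halves do not mix
  expect_true(all(lay$cx[lay$wavelength_nm == 695] < 1024))
  expect_true(all(lay$cx[lay$wavelength_nm == 830] >= 1024))
})

test_that("fiber irradiance and skin MPE reproduce the published safety numbers", {
  expect_equal(source_irradiance(source_spec()), 56.6, tolerance = 1e-3)
  expect_equal(source_irradiance(source_spec(power_mw = 0)), 0)
  expect_equal(source_irradiance(source_spec(power_mw = 1,
                                             fiber_tip_diameter_mm = 10)),
               1 / (pi * 0.25), tolerance = 1e-12)

  expect_equal(mpe_skin(695), 200)
  expect_equal(mpe_skin(700), 200)  # C_A continuous at the band edge
  expect_equal(mpe_skin(830), 363.94, tolerance = 1e-5)
  expect_error(mpe_skin(300), "band")

  # the default source complies at both wavelengths
  irr <- source_irradiance(source_spec())
  expect_lt(irr, mpe_skin(695))
  expect_lt(irr, mpe_skin(830))
})
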