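test_that("diffusion reflectance matches an independent closed-form evaluation", {
  expect_equal(mu_eff(0.01, 2.3), sqrt(3 * 0.01 * 2.31), tolerance = 1e-12)

  # monotone decreasing in mua and in rho
  m1 <- optical_medium(0.01, 2.3); m2 <- optical_medium(0.02, 2.3)
  expect_gt(diffusion_reflectance(m1, 30), diffusion_reflectance(m2, 30))
  expect_gt(diffusion_reflectance(m1, 20), diffusion_reflectance(m1, 30))

  # independent re-implementation of the extrapolated-boundary solution
  oracle <- function(mua, musp, rho) {
    mut <- mua + musp; z0 <- 1 / mut; D <- 1 / (3 * mut)
    A <- (1 + 0.431) / (1 - 0.431); zb <- 2 * A * D
    me <- sqrt(3 * mua * mut)
    r1 <- sqrt(z0^2 + rho^2); r2 <- sqrt((z0 + 2 * zb)^2 + rho^2)
    (z0 * (me + 1 / r1) * exp(-me * r1) / r1^2 +
       (z0 + 2 * zb) * (me + 1 / r2) * exp(-me * r2) / r2^2) / (4 * pi)
  }
  for (mua in c(0.005, 0.01, 0.05)) for (rho in c(10, 30)) {
    expect_equal(diffusion_reflectance(optical_medium(mua, 2.3), rho),
                 oracle(mua, 2.3, rho), tolerance = 1e-10)
  }
  expect_error(diffusion_reflectance(list(mua = 3, musp = 2.3), 30),
               "diffusive")
})

test_that("Intralipid scattering follows the empirical model with inverse consistency", {
  expect_equal(intralipid_musp(0, 695), 0)
  # independent evaluation at 1% stock volume fraction, 695 nm
  lam <- 0.695
  hand <- 10 * (0.016 * lam^-2.4) * (1 - (1.1 - 0.58 * lam))
  expect_equal(intralipid_musp(0.01, 695), hand, tolerance = 1e-12)

  cstar <- intralipid_concentration(2.3, 695)
  expect_equal(intralipid_musp(cstar, 695), 2.3, tolerance = 1e-12)
  expect_error(intralipid_musp(0.01, 1300), "validity")
})

test_that("titration presets reproduce the published absorption ranges exactly", {
  t0 <- ink_titration(0.01, specific_absorption = 1e-4, n_steps = 0)
  expect_equal(titration_mua_series(t0), 0.01)

  for (n in c(8, 9, 12)) {
    s <- titration_mua_series(titration_preset("baseline", n_steps = n))
    expect_equal(s[1], 0.00899)
    expect_equal(s[length(s)], 0.01100, tolerance = 1e-12)
    expect_true(all(diff(s) > 0))
    h <- titration_mua_series(titration_preset("high", n_steps = n))
    expect_equal(range(h), c(0.03366, 0.04639), tolerance = 1e-12)
  }
})

test_that("blood-phantom absorption is affine in oxygen saturation", {
  ph <- blood_phantom()
  ph0 <- blood_phantom(blood_volume_fraction = 0)
  expect_equal(blood_mua(ph0, 0.5, 695), ph0$background_mua)

  # at 830 nm HbO dominates, so full oxygenation absorbs more
  expect_gt(blood_mua(ph, 1, 830), blood_mua(ph, 0, 830))
  # at 695 nm HbR dominates: order reverses
  expect_lt(blood_mua(ph, 1, 695), blood_mua(ph, 0, 695))

  mid <- (blood_mua(ph, 0, 830) + blood_mua(ph, 1, 830)) / 2
  expect_equal(blood_mua(ph, 0.5, 830), mid, tolerance = 1e-14)
  expect_error(blood_mua(ph, 0.5, 550), "extinction")
})

test_that("deoxygenation course is monotone and its references read the course", {
  const <- deoxygenation_course(60, depletion_rate = 0)
  expect_true(all(const$so2 == 1))

  crs <- deoxygenation_course(300, fs = 5, n_reference_samples = 10)
  expect_equal(crs$so2[1], 1)
  expect_lte(crs$so2[length(crs$so2)], 0.01)
  expect_true(all(diff(crs$so2) <= 1e-12))
  expect_equal(nrow(crs$reference), 10L)
  look <- approx(crs$time_s, crs$so2, xout = crs$reference$time_s)$y
  expect_equal(crs$reference$so2, look, tolerance = 1e-12)
})

test_that("block-design generator honours its durations and inverts exactly", {
  d <- vft_design()
  sim <- vft_hemodynamics(d, fs = 5, seed = 2)
  expect_length(sim$time_s, 150 * 5)

  # zero response and zero noise give flat intensities
  flat <- vft_hemodynamics(vft_design(hbo_peak_mm = 0, cardiac_amp = 0,
                                      resp_amp = 0, mayer_amp = 0), fs = 5)
  expect_equal(diff(range(flat$intensity$value)), 0)

  # forward projection then MBLL inversion recovers the truth
  tab <- mbll_table(pathlength_mm = 30)
  i695 <- sim$intensity$value[sim$intensity$wavelength_nm == 695]
  i830 <- sim$intensity$value[sim$intensity$wavelength_nm == 830]
  hb <- mbll_invert(-log10(i695), -log10(i830), tab)
  expect_equal(hb$dhbo_mm, sim$dhbo_mm, tolerance = 1e-9)
  expect_equal(hb$dhbr_mm, sim$dhbr_mm, tolerance = 1e-9)
})

test_that("drift streams carry their programmed trend and reproduce under a seed", {
  clean <- drift_model(linear_rate_pct_h = 1, white_sd = 0)
  s <- drift_series(clean, 3600, fs = 5)
  expect_equal(linear_drift_rate(s$value, 5), 1, tolerance = 1e-6)

  still <- drift_series(drift_model(0, 0), 3600, fs = 1)
  expect_true(all(still$value == 1))
  expect_true(all(allan_deviation(still$value, 1)$adev == 0))

  a <- drift_series(drift_model(0.3, 1e-3, 1e-4), 600, 5, seed = 9)
  b <- drift_series(drift_model(0.3, 1e-3, 1e-4), 600, 5, seed = 9)
  expect_identical(a, b)

  # self-consistency: fitted drift of the default model within 10%
  d <- drift_series(drift_model(), 3600, fs = 5, seed = 4)
  expect_equal(linear_drift_rate(d$value, 5), 0.3, tolerance = 0.1)
})

test_that("white-noise Allan deviation falls as tau^(-1/2)", {
  set.seed(21)
  x <- 1 + rnorm(2e4, 0, 1e-3)
  ad <- allan_deviation(x, fs = 1, taus = c(1, 2, 5, 10, 20, 50))
  fit <- lm(log10(adev) ~ log10(tau_s), ad)
  expect_equal(unname(coef(fit)[2]), -0.5, tolerance = 0.05)
})
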