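test_that("two-state SNR matches hand computation and handles degenerate cases", {
  # mean 10, sample sd 0.16330 -> 20 log10(61.24) = 35.74 dB
  d <- c(10.0, 10.2, 9.8, 10.0)
  expect_equal(snr_two_state(diffs = d), 20 * log10(mean(d) / sd(d)))
  expect_equal(snr_two_state(diffs = d), 35.74, tolerance = 1e-3)

  expect_identical(snr_two_state(diffs = rep(3, 4)), Inf)
  expect_error(snr_two_state(diffs = c(-1, -2, -1.5, -1)), "swapped")
  expect_error(snr_two_state(diffs = 5), "repeats")

  # invariant to adding a common constant to both states
  a <- c(100.1, 99.9, 100.0, 100.2); b <- c(90.0, 90.1, 89.9, 90.0)
  expect_equal(snr_two_state(a, b), snr_two_state(a + 55, b + 55))
})

test_that("NEP and DOR formulas agree with independent one-line oracles", {
  h <- 6.62607015e-34; cc <- 2.99792458e8
  p695 <- nep_params(qe = 0.8406, wavelength_nm = 695)
  p830 <- nep_params(qe = 0.5333, wavelength_nm = 830)

  oracle_pix <- function(Q, lam, t, eta, BW) Q * h * cc / (lam * t * eta * sqrt(BW))
  expect_equal(nep_theoretical(p695)$nep_pix_w,
               oracle_pix(3.57, 695e-9, 0.025, 0.8406, 0.09),
               tolerance = 1e-12)
  expect_equal(nep_theoretical(p695)$nep_sum_w,
               sqrt(p695$n_pixels) * nep_theoretical(p695)$nep_pix_w,
               tolerance = 1e-12)
  expect_equal(nep_theoretical(nep_params(read_noise_e = 1e-12, qe = 0.8406,
                                          wavelength_nm = 695))$nep_pix_w,
               oracle_pix(1e-12, 695e-9, 0.025, 0.8406, 0.09), tolerance = 1e-12)

  # the published wavelength ratio survives even though the absolute scale
  # of the printed values does not follow from the formula
  ratio <- nep_theoretical(p830)$nep_pix_w / nep_theoretical(p695)$nep_pix_w
  expect_equal(ratio, (695 / 830) * (0.8406 / 0.5333), tolerance = 1e-12)
  expect_equal(ratio, 6.96 / 5.29, tolerance = 0.005)

  # actual NEP: Q_SNR1 = N MGV CG then the photometric relation
  oracle_act <- function(mgv, N, CG, lam, t, eta, BW)
    N * mgv * CG * h * cc / (lam * t * eta * sqrt(BW))
  expect_equal(nep_actual(2.0, p695),
               oracle_act(2.0, p695$n_pixels, 2.33, 695e-9, 0.025, 0.8406, 0.09),
               tolerance = 1e-12)
  expect_equal(nep_actual(0, p695), 0)
  expect_equal(nep_actual(4, p695), 2 * nep_actual(2, p695), tolerance = 1e-12)

  expect_equal(dynamic_optical_range(4095, 1.87), 10 * log10(4095 / 1.87),
               tolerance = 1e-12)
  expect_equal(dynamic_optical_range(5, 5), 0)
  expect_gt(dynamic_optical_range(5000, 1.87), dynamic_optical_range(4095, 1.87))
  expect_gt(dynamic_optical_range(4095, 1.87), dynamic_optical_range(4095, 1.92))
  expect_error(dynamic_optical_range(4095, 0), "mgv_min")
})

test_that("linear drift rate recovers programmed ramps", {
  fs <- 5
  t <- seq(0, 3600 - 1 / fs, by = 1 / fs)
  ramp <- 1 + 0.01 * (t - mean(t)) / 3600  # exact 1 %/h around mean 1
  expect_equal(linear_drift_rate(ramp, fs), 1, tolerance = 1e-9)
  expect_equal(linear_drift_rate(rep(5, 3600 * fs), fs), 0)
  expect_error(linear_drift_rate(rep(1, 100), fs), "shorter")
})

test_that("Allan deviation matches definitional hand cases and the triangle bound", {
  expect_true(all(allan_deviation(rep(2, 1000), 1)$adev == 0))

  # alternating +a/-a at tau = one sample: sigma_y = a sqrt(2)
  a <- 0.37
  x <- rep(c(a, -a), 500)
  ad <- allan_deviation(x, fs = 1, taus = 1, normalize = FALSE)
  expect_equal(ad$adev, a * sqrt(2), tolerance = 1e-12)

  # triangle property of the two-sample deviation
  set.seed(31)
  u <- 1 + rnorm(5000, 0, 1e-3)
  v <- 1 + cumsum(rnorm(5000, 0, 1e-5))
  taus <- c(1, 5, 20, 100)
  au <- allan_deviation(u, 1, taus, normalize = FALSE)$adev
  av <- allan_deviation(v, 1, taus, normalize = FALSE)$adev
  auv <- allan_deviation(u + v, 1, taus, normalize = FALSE)$adev
  expect_true(all(auv <= au + av + 1e-15))

  expect_error(allan_deviation(rnorm(10), 1, taus = 100), "empty")
})

test_that("three-sigma occupancy matches Gaussian theory and constructions", {
  expect_equal(sigma3_occupancy(rep(4, 10)), 100)
  set.seed(17)
  g <- rnorm(2e5)
  expect_equal(sigma3_occupancy(g), 99.73, tolerance = 1e-3)

  base <- rnorm(990)
  out <- c(base, rep(10 * sd(base), 10))
  expect_equal(sigma3_occupancy(out), 99, tolerance = 0.01)
})

test_that("the simulated SNR protocol behaves per the declared noise model", {
  g <- build_grid(3, 3, 30)
  m <- enumerate_channels(g)

  quiet <- run_snr_protocol(m, noiseless = TRUE, seed = 1)
  expect_true(all(quiet$snr_db == Inf))

  # analytic expectation at the operating level, oracle coded independently:
  # diff of two states, shot + read noise over the ROI
  spec <- sensor_spec()
  n_px <- roi_pixel_count(102)
  ea <- 335 * 2.33
  snr_expect <- function(e_per_px, db) {
    eb <- e_per_px / 10^(db / 10)
    va <- (e_per_px * n_px + 3.57^2 * n_px) / (2.33 * n_px)^2
    vb <- (eb * n_px + 3.57^2 * n_px) / (2.33 * n_px)^2
    20 * log10(((e_per_px - eb) / 2.33) / sqrt(va + vb))
  }
  res <- run_snr_protocol(m, perturbation_db = 3.5, n_repeats = 4, seed = 42)
  expect_equal(median(res$snr_db), snr_expect(ea, 3.5), tolerance = 0.12)

  # halving the operating power costs ~3 dB in the shot-limited regime
  res_half <- run_snr_protocol(m, state_a_mgv = 335 / 2,
                               perturbation_db = 3.5, n_repeats = 4, seed = 43)
  drop_expect <- snr_expect(ea, 3.5) - snr_expect(ea / 2, 3.5)
  expect_equal(median(res$snr_db) - median(res_half$snr_db), drop_expect,
               tolerance = 0.35)
  expect_equal(drop_expect, 3, tolerance = 0.15)
})

test_that("qc reports assemble and serialize", {
  g <- build_grid(1, 3, 30)
  snr <- run_snr_protocol(enumerate_channels(g), n_repeats = 4, seed = 3)
  dstream <- drift_series(drift_model(), 1200, 5, seed = 8)
  rep <- qc_report(snr, drift_stream = list(value = dstream$value, fs = 5))
  expect_s3_class(rep, "qc_report")
  expect_equal(unname(rep$dor_db["695"]), 33.40, tolerance = 0.005)
  expect_output(print(rep), "DOR")
  f <- tempfile(fileext = ".json")
  write_qc_report(rep, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$dor_db$`695`, unname(rep$dor_db["695"]))
})
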