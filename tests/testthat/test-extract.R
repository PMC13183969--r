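test_that("mean gray value equals the brute-force in-disc mean", {
  sp <- tiny_sensor()
  fr <- list(width = 64, height = 64, timestamp_s = 0, slot = 1L, group = 1L,
             adu = matrix(7, 64, 64))
  class(fr) <- "twin_frame"
  expect_equal(mean_gray_value(fr, roi_spec(32, 32, 5)), 7)

  # indicator construction: 100 inside the disc, 0 outside
  m <- matrix(0, 64, 64)
  px <- fnirstwin:::.disc_pixels(30, 40, 6)
  m[cbind(px[, "y"] + 1L, px[, "x"] + 1L)] <- 100
  fr$adu <- m
  expect_equal(mean_gray_value(fr, roi_spec(30, 40, 6)), 100)

  # random frame vs exhaustive enumeration oracle
  set.seed(12)
  fr$adu <- matrix(sample(0:4095, 64 * 64, TRUE), 64, 64)
  cx <- 20; cy <- 25; r <- 5
  acc <- c()
  for (x in 0:63) for (y in 0:63)
    if ((x - cx)^2 + (y - cy)^2 <= r^2) acc <- c(acc, fr$adu[y + 1, x + 1])
  expect_equal(mean_gray_value(fr, roi_spec(cx, cy, r)), mean(acc))

  expect_error(mean_gray_value(fr, roi_spec(2, 2, 5)), "bounds")
})

test_that("MGV is invariant to pixel permutation within the ROI", {
  fr <- list(width = 64, height = 64, timestamp_s = 0, slot = 1L, group = 1L,
             adu = matrix(sample(0:4095, 64 * 64, TRUE), 64, 64))
  class(fr) <- "twin_frame"
  roi <- roi_spec(32, 32, 8)
  before <- mean_gray_value(fr, roi)
  px <- fnirstwin:::.disc_pixels(32, 32, 8)
  idx <- cbind(px[, "y"] + 1L, px[, "x"] + 1L)
  fr$adu[idx] <- fr$adu[idx][sample(nrow(idx))]
  expect_equal(mean_gray_value(fr, roi), before)
})

test_that("demultiplexing assigns each cycle's slots to the right channels", {
  g <- build_grid(1, 3, 30)  # S D S: one detector, two sources, two channels
  sch <- build_tdm_schedule(g, 2, 25, 25)
  map <- enumerate_channels(g)
  sp <- noiseless_sensor()
  lay <- spot_layout(g$n_detectors, sp, radius_px = 5)
  rois <- rois_from_layout(lay)
  n_px <- roi_pixel_count(5)
  p1 <- operating_power(1000, 695, sp, n_px)  # MGV 1000, well below ceiling
  p2 <- 2 * p1
  pw_of_source <- c(p1, p2)
  power_fun <- function(t, ch, w) pw_of_source[map$source_id[match(ch, map$channel_id)]]
  frames <- simulate_stream(sch, map, power_fun, lay, sp, duration_s = 0.5)
  expect_length(frames, 10 * 2 / 2)  # 0.5 s / 100 ms cycles x 2 slots
  s <- demultiplex(frames, sch, map, rois)
  per_ch <- aggregate(mgv ~ channel_id + wavelength_nm, s, mean)
  m1 <- per_ch$mgv[per_ch$channel_id == 1 & per_ch$wavelength_nm == 695]
  m2 <- per_ch$mgv[per_ch$channel_id == 2 & per_ch$wavelength_nm == 695]
  expect_equal(m2 / m1, 2, tolerance = 1e-9)

  # series length = floor(n_frames / n_groups) per channel
  n_cycles <- length(frames) / sch$n_groups
  expect_equal(sum(s$channel_id == 1 & s$wavelength_nm == 695), n_cycles)
})

test_that("noiseless simulate-extract round trip recovers input powers", {
  g <- build_grid(1, 2, 30)
  sch <- build_tdm_schedule(g, 1, 25, 25)
  map <- enumerate_channels(g)
  sp <- noiseless_sensor()
  lay <- spot_layout(1, sp, radius_px = 5)
  n_px <- roi_pixel_count(5)
  p_in <- operating_power(1800, 695, sp, n_px)
  frames <- simulate_stream(sch, map, function(t, ch, w) rep(p_in, length(ch)),
                            lay, sp, duration_s = 1)
  expect_length(frames, 20L)  # 20 cycles of the single-slot 20 Hz schedule
  s <- demultiplex(frames, sch, map, rois_from_layout(lay))
  gain <- expected_electrons(1, 695, sp, n_px) / sp$conversion_gain
  rec <- s$mgv[s$wavelength_nm == 695] / gain
  expect_equal(rec, rep(p_in, length(rec)), tolerance = 1e-9)
})

test_that("one second of the 4-group schedule yields five samples per channel", {
  g <- build_grid(3, 3, 30)
  sch <- build_tdm_schedule(g, 4, 25, 25)
  map <- enumerate_channels(g)
  sp <- noiseless_sensor(width = 128, height = 128)
  lay <- spot_layout(g$n_detectors, sp, radius_px = 5)
  frames <- simulate_stream(sch, map, function(t, ch, w) rep(1e-9, length(ch)),
                            lay, sp, duration_s = 1)
  expect_length(frames, 20L)  # 5 cycles x 4 slots
  s <- demultiplex(frames, sch, map, rois_from_layout(lay))
  expect_true(all(table(s$channel_id, s$wavelength_nm) == 5))
})

test_that("missing frames become NA samples, never interpolations", {
  g <- build_grid(1, 2, 30)
  sch <- build_tdm_schedule(g, 1, 25, 25)
  map <- enumerate_channels(g)
  sp <- noiseless_sensor()
  lay <- spot_layout(1, sp, radius_px = 5)
  frames <- simulate_stream(sch, map, function(t, ch, w) rep(1e-9, length(ch)),
                            lay, sp, duration_s = 0.25)
  frames[3] <- list(NULL)  # drop one acquisition
  s <- demultiplex(frames, sch, map, rois_from_layout(lay))
  # exactly the dropped cycle is NA, at both wavelengths of the one channel
  expect_equal(sum(is.na(s$mgv)), 2L)
  expect_true(all(is.na(s$mgv[abs(s$time_s - 0.10) < 1e-9])))
})

test_that("source normalization cancels emitter intensity differences", {
  g <- build_grid(1, 3, 30)
  sch <- build_tdm_schedule(g, 2, 25, 25)
  map <- enumerate_channels(g)
  sp <- noiseless_sensor()
  lay <- spot_layout(1, sp, radius_px = 5)
  # source 2 emits twice the power of source 1 into the same medium
  pw <- operating_power(800, 695, sp, roi_pixel_count(5)) * c(1, 2)
  frames <- simulate_stream(sch, map, function(t, ch, w)
    pw[map$source_id[match(ch, map$channel_id)]], lay, sp, duration_s = 0.5)
  s <- demultiplex(frames, sch, map, rois_from_layout(lay))
  norm <- normalize_by_source(s, map, source_powers_mw = c(1, 2))
  v <- aggregate(value ~ channel_id + wavelength_nm, norm, mean)
  expect_equal(v$value[v$channel_id == 1], v$value[v$channel_id == 2],
               tolerance = 1e-9)
  expect_error(normalize_by_source(s, map, c(1, 0)), "power")
})

test_that("saturation flags count ceiling samples exactly", {
  s <- data.frame(time_s = 0:9 / 5, channel_id = 1, wavelength_nm = 695,
                  mgv = c(rep(100, 9), 4095), saturated = FALSE)
  attr(s, "ceiling_adu") <- 4095L
  class(s) <- c("channel_series", "data.frame")
  expect_warning(out <- flag_saturation(s), "saturation")
  expect_equal(sum(out$saturated), 1L)
  s$mgv[10] <- 90
  out2 <- flag_saturation(s)
  expect_equal(sum(out2$saturated), 0L)
})
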