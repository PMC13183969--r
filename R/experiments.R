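# End-to-end experiment runners: phantom truth -> sensor frames -> ROI
# extraction -> analysis, the rehearsal harness for the instrument's
# validation experiments.

#' Detector power that produces a target operating MGV
#'
#' Inverts the linear photoelectron relation: the optical power at which the
#' expected ROI mean equals `target_mgv` ADU above the pedestal.
#'
#' @param target_mgv Desired signal MGV, ADU.
#' @param wavelength_nm Wavelength.
#' @param spec A [sensor_spec()].
#' @param n_pixels ROI pixel count the power is spread over.
#' @return Power in watts.
#' @export
operating_power <- function(target_mgv, wavelength_nm, spec,
                            n_pixels = roi_pixel_count(102)) {
  stopifnot(target_mgv > 0)
  # expected_electrons(1 W, ..., n_pixels) is electrons/pixel per watt
  target_mgv * spec$conversion_gain /
    expected_electrons(1, wavelength_nm, spec, n_pixels)
}

#' Differential pathlength factor from the diffusion forward model
#'
#' The textbook definition: the differential pathlength `d(-ln R)/d mua`
#' evaluated at the medium's operating point, divided by the geometric
#' separation. Computed by central difference on
#' [diffusion_reflectance()].
#'
#' @param mua,musp Operating-point optical coefficients, mm^-1.
#' @param rho_mm Source-detector separation, mm.
#' @return DPF (dimensionless).
#' @export
differential_pathlength_factor <- function(mua, musp, rho_mm) {
  d <- 1e-7
  lo <- diffusion_reflectance(list(mua = mua - d, musp = musp), rho_mm)
  hi <- diffusion_reflectance(list(mua = mua + d, musp = musp), rho_mm)
  (-(log(hi) - log(lo)) / (2 * d)) / rho_mm
}

# shared scaffolding: grid, schedule, channel map, layout, ROIs
.twin_setup <- function(grid, n_groups, spec, radius_px) {
  schedule <- build_tdm_schedule(grid, n_groups = n_groups)
  map <- enumerate_channels(grid)
  layout <- spot_layout(grid$n_detectors, spec, radius_px = radius_px)
  list(schedule = schedule, map = map, layout = layout,
       rois = rois_from_layout(layout))
}

#' Simulated ink-titration experiment
#'
#' Drives the full chain for one of the phantom absorption ranges: per
#' titration step the CW diffusion model maps (mua, musp) at each
#' wavelength to detected power (scaled so the first step sits at the
#' operating MGV), the sensor twin renders TDM frames, and ROI extraction
#' recovers per-channel MGVs which are averaged within the step. The 830 nm
#' arm uses the same ink-driven mua series (India ink is spectrally flat
#' across this band) with the Intralipid scattering scaled to 830 nm by the
#' van Staveren model.
#'
#' @param preset Titration preset (see [titration_preset()]).
#' @param n_steps Ink additions after the base point (>= 7 recommended).
#' @param grid Optode grid (default the 3 x 11 array).
#' @param n_groups TDM groups.
#' @param cycles_per_step Acquisition cycles averaged per step.
#' @param target_mgv Operating MGV of the first step, ADU.
#' @param musp_695 Reduced scattering at 695 nm, mm^-1.
#' @param rho_mm Source-detector separation, mm.
#' @param spec A [sensor_spec()].
#' @param radius_px ROI radius.
#' @param seed Optional integer seed.
#' @return List: `steps` (data.frame `step`, `mua`, `wavelength_nm`,
#'   `channel_id`, `mgv`, `pct_change`, `sqrt_norm`), `r2_pct` and
#'   `r2_sqrt` (named per wavelength: pooled-channel regressions of percent
#'   MGV change, and of the square-root-transformed normalized signal,
#'   on mua).
#' @export
run_titration_experiment <- function(preset = "baseline", n_steps = 9,
                                     grid = build_grid(3, 11, 30),
                                     n_groups = 4, cycles_per_step = 5,
                                     target_mgv = 335, musp_695 = 2.3,
                                     rho_mm = grid$pitch_mm,
                                     spec = sensor_spec(), radius_px = 102,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tw <- .twin_setup(grid, n_groups, spec, radius_px)
  mua <- titration_mua_series(titration_preset(preset, n_steps = n_steps))
  wl <- c(695, 830)
  musp <- c("695" = musp_695,
            "830" = musp_695 * intralipid_musp(1, 830) / intralipid_musp(1, 695))
  n_px <- roi_pixel_count(radius_px)
  p0 <- vapply(wl, function(w) operating_power(target_mgv, w, spec, n_px), 0)
  names(p0) <- wl
  r0 <- vapply(wl, function(w)
    diffusion_reflectance(list(mua = mua[1], musp = musp[[as.character(w)]]),
                          rho_mm), 0)
  names(r0) <- wl
  rows <- list()
  for (k in seq_along(mua)) {
    pw <- vapply(wl, function(w) {
      rel <- diffusion_reflectance(
        list(mua = mua[k], musp = musp[[as.character(w)]]), rho_mm) /
        r0[[as.character(w)]]
      p0[[as.character(w)]] * rel
    }, 0)
    names(pw) <- wl
    acc <- demux_accumulator(tw$schedule, tw$map, tw$rois)
    simulate_stream(tw$schedule, tw$map,
                    function(t, ch, w) rep(pw[[as.character(w)]], length(ch)),
                    tw$layout, spec,
                    duration_s = cycles_per_step * tw$schedule$cycle_ms / 1000,
                    on_frame = acc$on_frame)
    s <- acc$series()
    ag <- stats::aggregate(mgv ~ channel_id + wavelength_nm, s, mean)
    ag$step <- k - 1L
    ag$mua <- mua[k]
    rows[[k]] <- ag
  }
  steps <- do.call(rbind, rows)
  steps$mgv <- steps$mgv - spec$offset_adu
  base <- steps[steps$step == 0L, ]
  key <- paste(steps$channel_id, steps$wavelength_nm)
  b <- base$mgv[match(key, paste(base$channel_id, base$wavelength_nm))]
  steps$pct_change <- 100 * (steps$mgv - b) / b
  steps$sqrt_norm <- sqrt_transform(pmax(steps$mgv, 0) / b)
  fit_by_wl <- function(col) {
    v <- vapply(wl, function(w) {
      d <- steps[steps$wavelength_nm == w, ]
      linear_fit_r2(d$mua, d[[col]])$r_squared
    }, 0)
    names(v) <- wl
    v
  }
  list(steps = steps, r2_pct = fit_by_wl("pct_change"),
       r2_sqrt = fit_by_wl("sqrt_norm"))
}

#' Simulated blood-phantom deoxygenation experiment
#'
#' Full rehearsal of the deoxygenation validation: a monotone oxygen
#' saturation course 1 -> 0 drives the phantom's absorption at both
#' wavelengths, the sensor twin acquires TDM frames, ROI extraction yields
#' dual-wavelength MGV series, and the pipeline recovers concentration and
#' saturation changes via the modified Beer-Lambert inversion with the DPF
#' taken from the diffusion model at the oxygenated baseline. Recovered
#' delta-SO2 is regressed on the blood-gas reference samples.
#'
#' Uses a minimal single-channel array by default: every channel of the
#' instrument sees the same stirred medium, so one channel carries the full
#' experiment.
#'
#' @param duration_s Course duration, seconds.
#' @param n_reference_samples Reference blood-gas draws (>= 10 for the
#'   validation regression).
#' @param ph A [blood_phantom()].
#' @param grid Optode grid (default 1 x 2: one source, one detector).
#' @param n_groups TDM groups (default 1; 20 Hz sampling).
#' @param target_mgv Operating MGV at the oxygenated baseline, ADU (signal
#'   above pedestal).
#' @param rho_mm Separation, mm.
#' @param spec A [sensor_spec()]; the default adds a 100 ADU pedestal so
#'   deeply attenuated deoxygenated-state signals stay unbiased.
#' @param radius_px ROI radius.
#' @param baseline_s Seconds of the oxygenated start used as the dOD
#'   baseline window.
#' @param seed Optional integer seed.
#' @return List: `r2` of recovered dSO2 vs reference SO2, `fit`
#'   (slope/intercept/R^2), `recovered` (data.frame `time_s`, `so2_ref`,
#'   `dso2_est` at reference times), `series` (full recovered course),
#'   `dpf` (per wavelength), `n_clipped`.
#' @export
run_bd_experiment <- function(duration_s = 120, n_reference_samples = 12,
                              ph = blood_phantom(),
                              grid = build_grid(1, 2, 30), n_groups = 1,
                              target_mgv = 335, rho_mm = grid$pitch_mm,
                              spec = sensor_spec(offset_adu = 100),
                              radius_px = 102, baseline_s = 5,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tw <- .twin_setup(grid, n_groups, spec, radius_px)
  fs <- tw$schedule$sampling_rate_hz
  course <- deoxygenation_course(duration_s, fs = fs,
                                 n_reference_samples = n_reference_samples)
  wl <- c(695, 830)
  n_px <- roi_pixel_count(radius_px)
  p0 <- vapply(wl, function(w) operating_power(target_mgv, w, spec, n_px), 0)
  names(p0) <- wl
  mua0 <- vapply(wl, function(w) blood_mua(ph, 1, w), 0)
  names(mua0) <- wl
  r0 <- vapply(wl, function(w)
    diffusion_reflectance(list(mua = mua0[[as.character(w)]], musp = ph$musp),
                          rho_mm), 0)
  names(r0) <- wl
  so2_at <- stats::approxfun(course$time_s, course$so2, rule = 2)
  power_fun <- function(t, ch, w) {
    mua <- blood_mua(ph, so2_at(t), w)
    rel <- diffusion_reflectance(list(mua = mua, musp = ph$musp), rho_mm) /
      r0[[as.character(w)]]
    rep(p0[[as.character(w)]] * rel, length(ch))
  }
  acc <- demux_accumulator(tw$schedule, tw$map, tw$rois)
  simulate_stream(tw$schedule, tw$map, power_fun, tw$layout, spec,
                  duration_s = duration_s, on_frame = acc$on_frame)
  s <- acc$series()
  ch1 <- tw$map$channel_id[1]
  get_w <- function(w) {
    d <- s[s$channel_id == ch1 & s$wavelength_nm == w, ]
    d <- d[order(d$time_s), ]
    pmax(d$mgv - spec$offset_adu, 1e-3)
  }
  i695 <- get_w(695); i830 <- get_w(830)
  t_s <- sort(unique(s$time_s[s$channel_id == ch1 & s$wavelength_nm == 695]))
  nb <- max(2, round(baseline_s * fs))
  dpf <- vapply(wl, function(w)
    differential_pathlength_factor(mua0[[as.character(w)]], ph$musp, rho_mm), 0)
  names(dpf) <- wl
  tab <- mbll_table(ph$extinction, dpf = dpf, pathlength_mm = rho_mm)
  d695 <- delta_od(i695, seq_len(nb))
  d830 <- delta_od(i830, seq_len(nb))
  hb <- mbll_invert(d695, d830, tab)
  so2 <- estimate_so2(hb$dhbo_mm, hb$dhbr_mm, thb0_mm = ph$thb_mm, so2_0 = 1)
  est_at <- stats::approx(t_s, so2$dso2, xout = course$reference$time_s,
                          rule = 2)$y
  fit <- linear_fit_r2(course$reference$so2, est_at)
  list(r2 = fit$r_squared, fit = fit,
       recovered = data.frame(time_s = course$reference$time_s,
                              so2_ref = course$reference$so2,
                              dso2_est = est_at),
       series = data.frame(time_s = t_s, dso2 = so2$dso2,
                           dhbo_mm = hb$dhbo_mm, dhbr_mm = hb$dhbr_mm),
       dpf = dpf, n_clipped = so2$n_clipped)
}

#' Simulated block-design (VFT) acquisition through the sensor twin
#'
#' Renders the task-evoked dual-wavelength intensities of
#' [vft_hemodynamics()] through the TDM sensor chain and recovers
#' concentration changes with [preprocess_channel()], returning truth and
#' recovery for comparison.
#'
#' @param design A [vft_design()].
#' @param grid Optode grid (default 1 x 2).
#' @param n_groups TDM groups (default 4, for the 5 Hz paradigm rate).
#' @param target_mgv Operating MGV, ADU.
#' @param spec A [sensor_spec()].
#' @param radius_px ROI radius (small radii keep test runs light).
#' @param filter Apply the band-pass inside the pipeline.
#' @param seed Optional integer seed.
#' @return List `truth` (from [vft_hemodynamics()]), `recovered`
#'   (`time_s`, `dhbo_mm`, `dhbr_mm`, `mask`), `correlation_hbo`.
#' @export
run_vft_experiment <- function(design = vft_design(),
                               grid = build_grid(1, 2, 30), n_groups = 4,
                               target_mgv = 335, spec = sensor_spec(),
                               radius_px = 20, filter = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tw <- .twin_setup(grid, n_groups, spec, radius_px)
  fs <- tw$schedule$sampling_rate_hz
  truth <- vft_hemodynamics(design, fs = fs)
  n_px <- roi_pixel_count(radius_px)
  wl <- c(695, 830)
  p0 <- vapply(wl, function(w) operating_power(target_mgv, w, spec, n_px), 0)
  names(p0) <- wl
  ifun <- lapply(wl, function(w) {
    d <- truth$intensity[truth$intensity$wavelength_nm == w, ]
    stats::approxfun(d$time_s, d$value, rule = 2)
  })
  names(ifun) <- wl
  power_fun <- function(t, ch, w)
    rep(p0[[as.character(w)]] * ifun[[as.character(w)]](t), length(ch))
  acc <- demux_accumulator(tw$schedule, tw$map, tw$rois)
  total_s <- design$pre_rest_s + design$task_s + design$post_rest_s
  simulate_stream(tw$schedule, tw$map, power_fun, tw$layout, spec,
                  duration_s = total_s, on_frame = acc$on_frame)
  s <- acc$series()
  ch1 <- tw$map$channel_id[1]
  get_w <- function(w) {
    d <- s[s$channel_id == ch1 & s$wavelength_nm == w, ]
    d$mgv[order(d$time_s)] - spec$offset_adu
  }
  i695 <- get_w(695); i830 <- get_w(830)
  base <- seq_len(round(design$pre_rest_s * fs))
  # normalized intensity: artifact amplitudes are fractions of baseline
  rec <- preprocess_channel(i695 / mean(i695[base]), i830 / mean(i830[base]),
                            fs, mbll_table(pathlength_mm = grid$pitch_mm),
                            baseline = base, filter = filter)
  t_s <- sort(unique(s$time_s[s$channel_id == ch1 & s$wavelength_nm == 695]))
  n <- min(length(t_s), length(truth$dhbo_mm))
  # compare on equal footing: the band-pass is part of the measurement chain
  truth_hbo <- if (filter) bandpass_filter(truth$dhbo_mm, fs) else truth$dhbo_mm
  ok <- !rec$mask[seq_len(n)]
  corr <- stats::cor(truth_hbo[seq_len(n)][ok], rec$dhbo_mm[seq_len(n)][ok])
  list(truth = truth,
       recovered = data.frame(time_s = t_s, dhbo_mm = rec$dhbo_mm,
                              dhbr_mm = rec$dhbr_mm, mask = rec$mask),
       correlation_hbo = corr)
}
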