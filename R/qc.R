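#' Two-state SNR in decibels
#'
#' `SNR = 20 log10(mean(dMGV) / sd(dMGV))` over repeated paired state
#' measurements, where `dMGV = MGV_A - MGV_B` per repeat and `sd` is the
#' sample standard deviation (n-1). A zero sd reports `Inf`; a negative mean
#' difference means the states are swapped and is an error.
#'
#' @param mgv_a,mgv_b Paired state means per repeat (equal length >= 2), or
#'   give `diffs` directly.
#' @param diffs Optional per-repeat differences `MGV_A - MGV_B`.
#' @return SNR in dB.
#' @export
snr_two_state <- function(mgv_a = NULL, mgv_b = NULL, diffs = mgv_a - mgv_b) {
  if (length(diffs) < 2) stop("need at least 2 repeats")
  m <- mean(diffs)
  if (m < 0) stop("negative mean difference: states A and B appear swapped")
  s <- stats::sd(diffs)
  if (s == 0) return(Inf)
  20 * log10(m / s)
}

#' Noise-equivalent-power parameters
#'
#' @param read_noise_e Read noise Q, electrons.
#' @param exposure_s Exposure time t, seconds.
#' @param qe Quantum efficiency fraction at `wavelength_nm`.
#' @param bw_hz Analysis bandwidth, Hz (default 0.09, the 0.01-0.1 Hz band).
#' @param n_pixels ROI pixel count N.
#' @param conversion_gain CG, electrons per ADU.
#' @param wavelength_nm Operating wavelength, nm.
#' @return An `nep_params` list.
#' @export
nep_params <- function(read_noise_e = 3.57, exposure_s = 0.025, qe,
                       bw_hz = 0.09, n_pixels = roi_pixel_count(102),
                       conversion_gain = 2.33, wavelength_nm) {
  stopifnot(read_noise_e > 0, exposure_s > 0, qe > 0, bw_hz > 0,
            n_pixels > 0, conversion_gain > 0, wavelength_nm > 0)
  structure(list(read_noise_e = read_noise_e, exposure_s = exposure_s,
                 qe = qe, bw_hz = bw_hz, n_pixels = n_pixels,
                 conversion_gain = conversion_gain,
                 wavelength_nm = wavelength_nm),
            class = "nep_params")
}

#' Theoretical noise-equivalent power
#'
#' Per-pixel `NEP_pix = Q h c / (lambda t eta sqrt(BW))` and the summed-ROI
#' `NEP_sum = sqrt(N) NEP_pix`. Literal evaluation of the read-noise-limited
#' photometric relation; see the methods vignette for the known absolute
#' scale caveat of the published figures (their 830/695 ratio is reproduced
#' to <0.5%).
#'
#' @param p An [nep_params()].
#' @param k Physical constants as [physical_constants()].
#' @return List `nep_pix_w`, `nep_sum_w` in W/sqrt(Hz).
#' @export
nep_theoretical <- function(p, k = physical_constants()) {
  stopifnot(inherits(p, "nep_params"))
  lam <- p$wavelength_nm * 1e-9
  pix <- p$read_noise_e * k$h * k$c / (lam * p$exposure_s * p$qe * sqrt(p$bw_hz))
  list(nep_pix_w = pix, nep_sum_w = sqrt(p$n_pixels) * pix)
}

#' Actual (measured) noise-equivalent power from the SNR=1 gray value
#'
#' `Q_SNR1 = N * MGV_SNR1 * CG` electrons over the ROI, then
#' `NEP_act = Q_SNR1 h c / (lambda t eta sqrt(BW))`.
#'
#' @param mgv_snr1 Mean gray value at SNR = 1, ADU.
#' @param p An [nep_params()].
#' @param k Physical constants.
#' @return NEP_act in W/sqrt(Hz).
#' @export
nep_actual <- function(mgv_snr1, p, k = physical_constants()) {
  stopifnot(mgv_snr1 >= 0, inherits(p, "nep_params"))
  q1 <- p$n_pixels * mgv_snr1 * p$conversion_gain
  lam <- p$wavelength_nm * 1e-9
  q1 * k$h * k$c / (lam * p$exposure_s * p$qe * sqrt(p$bw_hz))
}

#' Dynamic optical range
#'
#' `DOR = 10 log10(MGV_max / MGV_min)` dB: 33.40 dB for 4095/1.87 and
#' 33.29 dB for 4095/1.92.
#'
#' @param mgv_max,mgv_min Maximum non-saturating and minimum detectable MGV.
#' @return DOR in dB.
#' @export
dynamic_optical_range <- function(mgv_max, mgv_min) {
  if (any(mgv_min <= 0)) stop("mgv_min must be > 0")
  if (any(mgv_max < mgv_min)) stop("mgv_max must be >= mgv_min")
  10 * log10(mgv_max / mgv_min)
}

#' Linear drift rate in percent of mean per hour
#'
#' Least-squares line through the percent-of-mean signal
#' `y = 100 x / mean(x)`; the slope scaled to one hour.
#'
#' @param x Intensity series.
#' @param fs Sampling rate, Hz.
#' @param min_duration_s Minimum record length (default 600 s).
#' @return Drift rate, %/h (signed).
#' @export
linear_drift_rate <- function(x, fs, min_duration_s = 600) {
  n <- length(x)
  if (n / fs < min_duration_s)
    stop("record shorter than ", min_duration_s, " s")
  if (mean(x) == 0) stop("zero-mean series: percent-of-mean undefined")
  t <- (seq_len(n) - 1) / fs
  y <- 100 * x / mean(x)
  unname(stats::coef(stats::lm.fit(cbind(1, t), y))[2]) * 3600
}

#' Overlapping Allan deviation
#'
#' Two-sample (Allan) deviation of the percent-of-mean signal versus
#' averaging time tau: `sigma_y(tau)^2 = <(ybar_{k+1} - ybar_k)^2> / 2` over
#' all overlapping pairs of adjacent tau-long averages. White noise falls as
#' `tau^-1/2`; flat or rising segments reveal flicker and drift.
#'
#' @param x Intensity series.
#' @param fs Sampling rate, Hz.
#' @param taus Averaging times, seconds (each <= duration/3); default a
#'   log-spaced grid.
#' @param normalize Divide by the mean and scale to percent first (default
#'   TRUE).
#' @return Data frame `tau_s`, `adev`.
#' @export
allan_deviation <- function(x, fs, taus = NULL, normalize = TRUE) {
  n <- length(x)
  if (normalize) x <- 100 * x / mean(x)
  if (is.null(taus)) {
    mmax <- floor(n / 3)
    ms <- unique(round(10^seq(0, log10(mmax), length.out = 20)))
    taus <- ms / fs
  }
  taus <- taus[taus * fs >= 1 & taus * fs <= n / 3]
  if (!length(taus)) stop("tau grid empty after the tau <= duration/3 cut")
  cs <- c(0, cumsum(x))
  out <- vapply(taus, function(tau) {
    m <- round(tau * fs)
    a <- (cs[(m + 1):(n + 1)] - cs[1:(n - m + 1)]) / m  # overlapping means
    d <- a[(m + 1):length(a)] - a[1:(length(a) - m)]
    sqrt(mean(d^2) / 2)
  }, 0)
  data.frame(tau_s = taus, adev = out)
}

#' Percent of samples within three standard deviations of the mean
#'
#' @param x Series (n >= 2); mean and sd over the whole record.
#' @return Occupancy in percent (0-100). A constant series returns 100.
#' @export
sigma3_occupancy <- function(x) {
  if (length(x) < 2) stop("need at least 2 samples")
  s <- stats::sd(x)
  if (s == 0) return(100)
  100 * mean(abs(x - mean(x)) <= 3 * s)
}

#' Drift metrics triple
#'
#' @param x Intensity series.
#' @param fs Sampling rate, Hz.
#' @return List `linear_rate_pct_h`, `allan` (data frame), `sigma3_pct`.
#' @export
drift_metrics <- function(x, fs) {
  list(linear_rate_pct_h = linear_drift_rate(x, fs),
       allan = allan_deviation(x, fs),
       sigma3_pct = sigma3_occupancy(x))
}

#' Simulated two-state SNR protocol
#'
#' Emulates the shuttered two-phantom SNR characterization: against a
#' >60 dB-loss background, each channel is measured in State A (operating
#' level) and State B (A attenuated by a calibrated 3-4 dB optical
#' perturbation), repeated `n_repeats` times, and scored with
#' [snr_two_state()]. State MGVs are sampled over the full ROI with the
#' sensor's Poisson/Gaussian photon-transfer model.
#'
#' @param map A [enumerate_channels()] channel map.
#' @param spec A [sensor_spec()].
#' @param state_a_mgv Target State A operating level, ADU (default 335, a
#'   forehead-like level).
#' @param perturbation_db Optical perturbation; scalar or length-2 range
#'   from which each channel draws uniformly (default `c(3, 4)`).
#' @param n_repeats Paired repeats per channel (default 4).
#' @param wavelengths_nm Wavelengths to score.
#' @param radius_px ROI radius.
#' @param noiseless Disable shot and read noise (states are then exact and
#'   the SNR is the `Inf` sentinel on every channel).
#' @param seed Optional integer seed.
#' @return Data frame `channel_id`, `wavelength_nm`, `snr_db`.
#' @export
run_snr_protocol <- function(map, spec = sensor_spec(), state_a_mgv = 335,
                             perturbation_db = c(3, 4), n_repeats = 4,
                             wavelengths_nm = c(695, 830), radius_px = 102,
                             noiseless = FALSE, seed = NULL) {
  stopifnot(inherits(map, "channel_map"))
  if (!is.null(seed)) set.seed(seed)
  n_px <- roi_pixel_count(radius_px)
  mu_a <- state_a_mgv * spec$conversion_gain  # electrons/pixel in State A
  rows <- list()
  for (w in wavelengths_nm) for (ci in map$channel_id) {
    db <- if (length(perturbation_db) == 2)
      stats::runif(1, perturbation_db[1], perturbation_db[2])
    else perturbation_db
    mu_b <- mu_a / 10^(db / 10)
    if (noiseless) {
      a <- rep(mu_a / spec$conversion_gain, n_repeats)
      b <- rep(mu_b / spec$conversion_gain, n_repeats)
    } else {
      a <- roi_mgv_sample(mu_a, n_px, spec, n = n_repeats)
      b <- roi_mgv_sample(mu_b, n_px, spec, n = n_repeats)
    }
    rows[[length(rows) + 1L]] <-
      data.frame(channel_id = ci, wavelength_nm = w, snr_db = snr_two_state(a, b))
  }
  do.call(rbind, rows)
}

#' Aggregate instrument QC report
#'
#' Bundles the characterization of a simulated instrument: per-channel SNR,
#' theoretical NEP per wavelength, DOR from supplied MGV bounds, and the
#' drift metric triple of a supplied stability stream.
#'
#' @param snr Data frame from [run_snr_protocol()].
#' @param spec A [sensor_spec()].
#' @param mgv_min Named per-wavelength minimum detectable MGV.
#' @param drift_stream Optional list (`value`, `fs`) for drift metrics.
#' @return A `qc_report` list; `print()` renders the human-readable form and
#'   [write_qc_report()] the JSON form.
#' @export
qc_report <- function(snr, spec = sensor_spec(),
                      mgv_min = c("695" = 1.87, "830" = 1.92),
                      drift_stream = NULL) {
  wl <- as.numeric(names(spec$qe))
  nep <- lapply(wl, function(w)
    nep_theoretical(nep_params(read_noise_e = spec$read_noise_e,
                               exposure_s = spec$exposure_s,
                               qe = .qe_at(spec, w),
                               conversion_gain = spec$conversion_gain,
                               wavelength_nm = w)))
  names(nep) <- wl
  dor <- vapply(names(mgv_min), function(w)
    dynamic_optical_range(spec$ceiling_adu, mgv_min[[w]]), 0)
  drift <- if (!is.null(drift_stream))
    drift_metrics(drift_stream$value, drift_stream$fs)
  structure(list(snr = snr,
                 snr_summary = c(min_db = min(snr$snr_db),
                                 mean_db = mean(snr$snr_db)),
                 nep_theoretical = nep, dor_db = dor, drift = drift),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Instrument QC report\n")
  cat(sprintf("  SNR: min %.2f dB, mean %.2f dB over %d channel-wavelengths\n",
              x$snr_summary["min_db"], x$snr_summary["mean_db"], nrow(x$snr)))
  for (w in names(x$nep_theoretical))
    cat(sprintf("  NEP_sum (theoretical, %s nm): %.3g pW/sqrt(Hz)\n",
                w, 1e12 * x$nep_theoretical[[w]]$nep_sum_w))
  for (w in names(x$dor_db))
    cat(sprintf("  DOR (%s nm): %.2f dB\n", w, x$dor_db[[w]]))
  if (!is.null(x$drift))
    cat(sprintf("  Drift: %.3f %%/h linear, %.2f%% within 3 sigma\n",
                x$drift$linear_rate_pct_h, x$drift$sigma3_pct))
  invisible(x)
}
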