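#' Optical medium (absorption and reduced scattering)
#'
#' @param mua Absorption coefficient, mm^-1 (scalar or named per wavelength).
#' @param musp Transport (reduced) scattering coefficient, mm^-1.
#' @return An `optical_medium` list. Warns when `musp/mua < 10`, where the
#'   diffusion approximation starts to degrade.
#' @export
optical_medium <- function(mua, musp) {
  if (any(mua < 0)) stop("mua must be >= 0")
  if (any(musp <= 0)) stop("musp must be > 0")
  if (any(musp / pmax(mua, .Machine$double.eps) < 10))
    warning("musp/mua < 10: diffusion approximation questionable")
  structure(list(mua = mua, musp = musp), class = "optical_medium")
}

#' Effective attenuation coefficient
#'
#' `sqrt(3 mua (mua + musp))`, the CW diffusion decay constant.
#'
#' @param mua,musp Optical coefficients, mm^-1.
#' @return mu_eff in mm^-1.
#' @export
mu_eff <- function(mua, musp) sqrt(3 * mua * (mua + musp))

#' Semi-infinite CW diffuse reflectance
#'
#' Steady-state reflectance of a pencil beam on a semi-infinite turbid
#' medium, extrapolated-boundary solution (isotropic point source at depth
#' `z0 = 1/(mua+musp)` plus negative image source above the extrapolated
#' boundary at `z = -(z0 + 2 zb)`, `zb = 2 A D`). The internal-reflection
#' parameter `A = (1+R_eff)/(1-R_eff)` uses `R_eff = 0.431` for a liquid
#' phantom of refractive index 1.33 by default. Only relative intensity is
#' meaningful; the absolute scale carries no calibration.
#'
#' @param medium An [optical_medium()], or `mua` may be given directly.
#' @param rho_mm Source-detector separation, mm.
#' @param r_eff Effective internal reflection coefficient.
#' @return Relative detected power (arbitrary units), strictly decreasing in
#'   both `mua` and `rho_mm`.
#' @export
diffusion_reflectance <- function(medium, rho_mm, r_eff = 0.431) {
  stopifnot(rho_mm > 0)
  mua <- medium$mua; musp <- medium$musp
  if (any(musp <= mua)) stop("medium is not diffusive (musp <= mua)")
  mut <- mua + musp
  D <- 1 / (3 * mut)
  z0 <- 1 / mut
  A <- (1 + r_eff) / (1 - r_eff)
  zb <- 2 * A * D
  me <- mu_eff(mua, musp)
  r1 <- sqrt(z0^2 + rho_mm^2)
  r2 <- sqrt((z0 + 2 * zb)^2 + rho_mm^2)
  (1 / (4 * pi)) * (z0 * (me + 1 / r1) * exp(-me * r1) / r1^2 +
                    (z0 + 2 * zb) * (me + 1 / r2) * exp(-me * r2) / r2^2)
}

#' Intralipid reduced scattering (van Staveren empirical model)
#'
#' Empirical wavelength dependence for Intralipid-10%:
#' `mus = 0.016 lambda^-2.4` mm^-1 per (mL stock / L suspension) and
#' anisotropy `g = 1.1 - 0.58 lambda` with `lambda` in micrometres;
#' `musp = mus (1 - g)` scales linearly with concentration.
#'
#' @param concentration Volume fraction of Intralipid-10% stock in the
#'   suspension (0-1).
#' @param wavelength_nm Wavelength, 400-1100 nm.
#' @return musp in mm^-1.
#' @export
intralipid_musp <- function(concentration, wavelength_nm) {
  if (any(concentration < 0)) stop("concentration must be >= 0")
  if (any(wavelength_nm < 400 | wavelength_nm > 1100))
    stop("wavelength outside the 400-1100 nm validity range")
  lam <- wavelength_nm / 1000
  mus_per_mlL <- 0.016 * lam^-2.4
  g <- 1.1 - 0.58 * lam
  (concentration * 1000) * mus_per_mlL * (1 - g)
}

#' @rdname intralipid_musp
#' @param target_musp Desired musp in mm^-1; returns the stock volume
#'   fraction achieving it at `wavelength_nm`.
#' @export
intralipid_concentration <- function(target_musp, wavelength_nm) {
  stopifnot(target_musp >= 0)
  target_musp / intralipid_musp(1, wavelength_nm)
}

#' Ink titration description and absorption series
#'
#' Stepwise India-ink addition into a scattering phantom: step `k` has
#' `mua_k = base_mua + k * increment_ul * specific_absorption`. The presets
#' reproduce the published phantom validation ranges exactly at their
#' endpoints (the per-microlitre specific absorption is calibrated from the
#' endpoints and step count).
#'
#' @param base_mua Starting absorption, mm^-1.
#' @param increment_ul Ink volume added per step, microlitres.
#' @param specific_absorption Absorption added per microlitre of ink,
#'   mm^-1/uL.
#' @param n_steps Number of additions after the base point.
#' @return An `ink_titration` list.
#' @export
ink_titration <- function(base_mua, increment_ul = 2, specific_absorption,
                          n_steps) {
  stopifnot(base_mua >= 0, increment_ul > 0, specific_absorption > 0,
            n_steps >= 0)
  structure(list(base_mua = base_mua, increment_ul = increment_ul,
                 specific_absorption = specific_absorption,
                 n_steps = as.integer(n_steps)),
            class = "ink_titration")
}

#' @rdname ink_titration
#' @param preset `"baseline"` (mua 0.00899-0.01100 mm^-1),
#'   `"low"` (0.01192-0.01254) or `"high"` (0.03366-0.04639), the three
#'   published validation ranges at 695 nm; `n_steps` additions span the
#'   range with equal increments.
#' @export
titration_preset <- function(preset = c("baseline", "low", "high"),
                             n_steps = 9, increment_ul = 2) {
  preset <- match.arg(preset)
  ends <- switch(preset,
                 baseline = c(0.00899, 0.01100),
                 low = c(0.01192, 0.01254),
                 high = c(0.03366, 0.04639))
  ink_titration(base_mua = ends[1], increment_ul = increment_ul,
                specific_absorption = (ends[2] - ends[1]) /
                  (n_steps * increment_ul),
                n_steps = n_steps)
}

#' @rdname ink_titration
#' @param tit An `ink_titration`.
#' @export
titration_mua_series <- function(tit) {
  stopifnot(inherits(tit, "ink_titration"))
  tit$base_mua + (0:tit$n_steps) * tit$increment_ul * tit$specific_absorption
}

#' Hemoglobin extinction coefficients
#'
#' Decadic molar extinction coefficients of oxy- and deoxyhemoglobin in
#' mm^-1 mM^-1 at the two operating wavelengths, from the standard compiled
#' in-vitro spectra (Prahl's tabulation, converted from cm^-1 M^-1).
#' At 830 nm HbO absorbs more strongly than HbR; at 695 nm the order is
#' reversed, which is what makes the dual-wavelength inversion well posed.
#'
#' @return Matrix with rows `HbO`, `HbR` and columns named by wavelength nm.
#' @export
hemoglobin_extinction <- function() {
  rbind(HbO = c("695" = 0.0283, "830" = 0.0974),
        HbR = c("695" = 0.19231, "830" = 0.0693))
}

#' Blood-doped phantom description
#'
#' A stirred Intralipid/saline suspension doped with whole blood; absorption
#' follows the hemoglobin oxygen saturation. With 5% blood by volume and
#' whole-blood total hemoglobin ~2.3 mM, the mixture tHb is 0.115 mM.
#'
#' @param blood_volume_fraction Blood volume fraction (default 0.05).
#' @param whole_blood_thb_mm Whole-blood total hemoglobin, mM.
#' @param background_mua Non-hemoglobin background absorption, mm^-1.
#' @param musp Reduced scattering of the mixture, mm^-1 (default 2.3).
#' @param extinction Extinction table as [hemoglobin_extinction()].
#' @return A `blood_phantom` list; `thb_mm` is the mixture concentration.
#' @export
blood_phantom <- function(blood_volume_fraction = 0.05,
                          whole_blood_thb_mm = 2.3,
                          background_mua = 0.002, musp = 2.3,
                          extinction = hemoglobin_extinction()) {
  stopifnot(blood_volume_fraction >= 0, blood_volume_fraction <= 1,
            whole_blood_thb_mm >= 0, background_mua >= 0, musp > 0,
            all(extinction > 0))
  structure(list(blood_volume_fraction = blood_volume_fraction,
                 thb_mm = blood_volume_fraction * whole_blood_thb_mm,
                 background_mua = background_mua, musp = musp,
                 extinction = extinction),
            class = "blood_phantom")
}

#' Absorption of the blood phantom at a given oxygen saturation
#'
#' `mua = ln(10) tHb (so2 eps_HbO + (1 - so2) eps_HbR) + background`; the
#' `ln(10)` converts the decadic extinction coefficients to a natural-log
#' absorption coefficient. Affine in `so2`.
#'
#' @param ph A [blood_phantom()].
#' @param so2 Oxygen saturation fraction in `[0, 1]` (vectorized).
#' @param wavelength_nm Wavelength with an extinction entry.
#' @return mua in mm^-1.
#' @export
blood_mua <- function(ph, so2, wavelength_nm) {
  stopifnot(inherits(ph, "blood_phantom"), all(so2 >= 0), all(so2 <= 1))
  w <- as.character(wavelength_nm)
  if (!w %in% colnames(ph$extinction))
    stop("no extinction entry for wavelength ", wavelength_nm, " nm")
  log(10) * ph$thb_mm *
    (so2 * ph$extinction["HbO", w] + (1 - so2) * ph$extinction["HbR", w]) +
    ph$background_mua
}

#' Deoxygenation course with reference samples
#'
#' A monotone non-increasing oxygen-saturation course from 1.0 to ~0,
#' emulating dithionite-driven deoxygenation of a stirred blood phantom with
#' periodic blood-gas reference draws. The default shape is a logistic decay
#' rescaled to hit exactly 1 at `t = 0` and 0 at `t = duration`; reference
#' samples read the course exactly, optionally with analyzer noise.
#'
#' @param duration_s Course duration, seconds.
#' @param fs Sampling rate of the returned course, Hz.
#' @param n_reference_samples Number of evenly spaced reference draws.
#' @param steepness Logistic steepness parameter (log-odds span over the
#'   course; larger is a sharper transition).
#' @param depletion_rate Set to 0 for a constant course at SO2 = 1.
#' @param analyzer_sd Gaussian sd of reference-analyzer noise (fraction).
#' @return List with `time_s`, `so2` (the course), and data.frame
#'   `reference` (`time_s`, `so2`).
#' @export
deoxygenation_course <- function(duration_s, fs = 5, n_reference_samples = 10,
                                 steepness = 12, depletion_rate = 1,
                                 analyzer_sd = 0) {
  stopifnot(duration_s > 0, fs > 0, n_reference_samples >= 0)
  t <- seq(0, duration_s, by = 1 / fs)
  if (depletion_rate == 0) {
    so2 <- rep(1, length(t))
  } else {
    f <- stats::plogis(-steepness * (t / duration_s - 0.5))
    so2 <- (f - f[length(f)]) / (f[1] - f[length(f)])
  }
  tr <- if (n_reference_samples > 0)
    seq(0, duration_s, length.out = n_reference_samples) else numeric()
  ref <- stats::approx(t, so2, xout = tr, rule = 2)$y
  if (analyzer_sd > 0)
    ref <- pmin(pmax(ref + stats::rnorm(length(ref), 0, analyzer_sd), 0), 1)
  list(time_s = t, so2 = so2,
       reference = data.frame(time_s = tr, so2 = ref))
}

#' Canonical double-gamma hemodynamic response kernel
#'
#' @param t_s Time grid, seconds.
#' @param peak_s,under_s Response and undershoot delays.
#' @param ratio Undershoot amplitude ratio.
#' @return Kernel values, peak-normalized to 1.
#' @export
hemodynamic_kernel <- function(t_s, peak_s = 6, under_s = 16, ratio = 1/6) {
  a1 <- peak_s; a2 <- under_s
  h <- stats::dgamma(t_s, shape = a1, rate = 1) -
    ratio * stats::dgamma(t_s, shape = a2, rate = 1)
  h / max(h)
}

#' Block-design task description
#'
#' Rest-task-rest block paradigm (default 30 s pre-task rest, 60 s task,
#' 60 s post-task rest) with a canonical hemodynamic response, opposite-sign
#' HbR, physiological nuisance sinusoids and optional motion artifacts.
#'
#' @param pre_rest_s,task_s,post_rest_s Epoch durations, seconds.
#' @param hbo_peak_mm Peak HbO concentration change, mM.
#' @param hbr_ratio HbR peak as a (negative) fraction of the HbO peak.
#' @param cardiac_hz,resp_hz,mayer_hz Nuisance frequencies, Hz.
#' @param cardiac_amp,resp_amp,mayer_amp Nuisance amplitudes as fractions of
#'   `hbo_peak_mm`.
#' @param motion_events Data frame (`time_s`, `amplitude`, `duration_s`) of
#'   intensity spikes injected into the optical signal; `NULL` for none.
#' @return A `vft_design` list.
#' @export
vft_design <- function(pre_rest_s = 30, task_s = 60, post_rest_s = 60,
                       hbo_peak_mm = 1e-3, hbr_ratio = -1/3,
                       cardiac_hz = 1, resp_hz = 0.3, mayer_hz = 0.1,
                       cardiac_amp = 0.1, resp_amp = 0.1, mayer_amp = 0.1,
                       motion_events = NULL) {
  stopifnot(pre_rest_s > 0, task_s > 0, post_rest_s > 0)
  structure(as.list(environment()), class = "vft_design")
}

#' Simulate block-design hemodynamics and contaminated intensities
#'
#' Generates the ground-truth concentration changes (task boxcar convolved
#' with the double-gamma kernel; HbR scaled opposite-signed), adds
#' physiological sinusoids with random phases, forward-projects to
#' dual-wavelength optical intensities through the Beer-Lambert relation
#' `I = I0 10^-(eps_HbO dHbO + eps_HbR dHbR) L DPF`, and injects scheduled
#' motion-artifact intensity excursions.
#'
#' @param design A [vft_design()].
#' @param fs Sampling rate, Hz.
#' @param extinction Extinction table, mm^-1 mM^-1.
#' @param dpf Differential pathlength factor per wavelength (named).
#' @param pathlength_mm Source-detector separation, mm.
#' @param i0 Baseline intensity per wavelength.
#' @param seed Optional integer seed for the random phases.
#' @return List with `time_s`; the task-evoked components `dhbo_task_mm`,
#'   `dhbr_task_mm`; the full tissue truth `dhbo_mm`, `dhbr_mm` (evoked plus
#'   physiological oscillations, which are genuine hemoglobin fluctuations);
#'   and `intensity`: data.frame (`time_s`, `wavelength_nm`, `value`), the
#'   forward-projected optical signal carrying motion artifacts.
#' @export
vft_hemodynamics <- function(design, fs = 5,
                             extinction = hemoglobin_extinction(),
                             dpf = c("695" = 6, "830" = 6),
                             pathlength_mm = 30, i0 = c("695" = 1, "830" = 1),
                             seed = NULL) {
  stopifnot(inherits(design, "vft_design"), fs > 0)
  if (!is.null(seed)) set.seed(seed)
  total <- design$pre_rest_s + design$task_s + design$post_rest_s
  n <- round(total * fs)
  t <- (seq_len(n) - 1) / fs
  box <- as.numeric(t >= design$pre_rest_s &
                      t < design$pre_rest_s + design$task_s)
  ker <- hemodynamic_kernel(seq(0, 30, by = 1 / fs))
  resp <- stats::convolve(box, rev(ker), type = "open")[seq_len(n)]
  resp <- resp / max(resp)
  dhbo <- design$hbo_peak_mm * resp
  dhbr <- design$hbr_ratio * dhbo
  phase <- stats::runif(3, 0, 2 * pi)
  nuis <- design$hbo_peak_mm *
    (design$cardiac_amp * sin(2 * pi * design$cardiac_hz * t + phase[1]) +
     design$resp_amp * sin(2 * pi * design$resp_hz * t + phase[2]) +
     design$mayer_amp * sin(2 * pi * design$mayer_hz * t + phase[3]))
  dhbo_total <- dhbo + nuis
  dhbr_total <- dhbr - nuis / 3  # arterial oscillations couple weakly into HbR
  wl <- colnames(extinction)
  inten <- do.call(rbind, lapply(wl, function(w) {
    od <- (extinction["HbO", w] * dhbo_total +
             extinction["HbR", w] * dhbr_total) *
      pathlength_mm * dpf[w]
    v <- unname(i0[w]) * 10^(-od)
    data.frame(time_s = t, wavelength_nm = as.numeric(w), value = v)
  }))
  if (!is.null(design$motion_events)) {
    for (j in seq_len(nrow(design$motion_events))) {
      ev <- design$motion_events[j, ]
      hit <- inten$time_s >= ev$time_s &
        inten$time_s < ev$time_s + ev$duration_s
      inten$value[hit] <- inten$value[hit] * (1 + ev$amplitude)
    }
  }
  list(time_s = t, dhbo_task_mm = dhbo, dhbr_task_mm = dhbr,
       dhbo_mm = dhbo_total, dhbr_mm = dhbr_total, intensity = inten)
}

#' Instrument drift model and stream generator
#'
#' @param linear_rate_pct_h Deterministic linear drift, percent of mean per
#'   hour.
#' @param white_sd Relative sd of white noise.
#' @param flicker_sd Relative sd of 1/f (flicker) noise, generated by
#'   spectral shaping of white noise with amplitude proportional to
#'   `f^-1/2`.
#' @return A `drift_model` list.
#' @export
drift_model <- function(linear_rate_pct_h = 0.3, white_sd = 1e-3,
                        flicker_sd = 0) {
  structure(list(linear_rate_pct_h = linear_rate_pct_h,
                 white_sd = white_sd, flicker_sd = flicker_sd),
            class = "drift_model")
}

#' @rdname drift_model
#' @param model A `drift_model`.
#' @param duration_s,fs Stream duration (s) and sampling rate (Hz).
#' @param seed Optional integer seed.
#' @return `drift_series()` returns a list `time_s`, `value`: a mean-one
#'   normalized intensity stream carrying the configured trend and noise.
#' @export
drift_series <- function(model, duration_s, fs, seed = NULL) {
  stopifnot(inherits(model, "drift_model"), duration_s > 0, fs > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  x <- 1 + (model$linear_rate_pct_h / 100) * (t - mean(t)) / 3600
  if (model$white_sd > 0) x <- x + stats::rnorm(n, 0, model$white_sd)
  if (model$flicker_sd > 0) {
    w <- stats::rnorm(n)
    W <- stats::fft(w)
    f <- c(1, seq_len(n - 1))  # avoid dividing DC by zero
    shape <- 1 / sqrt(pmin(f, n - f + 1))
    fl <- Re(stats::fft(W * shape, inverse = TRUE)) / n
    fl <- fl - mean(fl)
    x <- x + model$flicker_sd * fl / stats::sd(fl)
  }
  list(time_s = t, value = x)
}
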