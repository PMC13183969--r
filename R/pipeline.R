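#' Prune non-responsive channels from a titration experiment
#'
#' A channel that shows no decrease in signal at either wavelength while the
#' absorber is titrated up is not seeing the medium and is removed: the
#' fitted slope of signal versus absorption must be negative at at least one
#' wavelength for the channel to be retained (pruning requires a
#' non-negative slope at both).
#'
#' @param values Data frame with `channel_id`, `wavelength_nm`, `mua`,
#'   `value` (one row per titration step).
#' @return List `retained`, `pruned` (channel id vectors) and `slopes`
#'   (data.frame of fitted slopes).
#' @export
prune_nonresponsive <- function(values) {
  stopifnot(all(c("channel_id", "wavelength_nm", "mua", "value") %in%
                  names(values)))
  if (length(unique(values$mua)) < 3)
    stop("need at least 3 titration points")
  sl <- do.call(rbind, lapply(split(values,
                                    values[c("channel_id", "wavelength_nm")],
                                    drop = TRUE), function(d) {
    data.frame(channel_id = d$channel_id[1], wavelength_nm = d$wavelength_nm[1],
               slope = unname(stats::coef(stats::lm(value ~ mua, d))[2]))
  }))
  rownames(sl) <- NULL
  # numeric guard: a fitted slope of a constant series can be -1e-18
  nonneg <- sl$slope >= -1e-12 * pmax(1, abs(sl$slope))
  flat <- tapply(nonneg, sl$channel_id, all)
  pruned <- as.integer(names(flat)[flat])
  list(retained = setdiff(unique(values$channel_id), pruned),
       pruned = pruned, slopes = sl)
}

#' Detect motion artifacts by windowed change thresholds
#'
#' Homer-style windowed change detector: over a sliding evaluation window of
#' `window_s` seconds, a sample is flagged when the peak-to-peak signal
#' change within its window exceeds `std_thresh` times the channel's noise
#' scale (the robust sd of sample-to-sample differences, 1.4826 MAD) or the
#' amplitude excursion exceeds `amp_thresh` (on whatever intensity scale the
#' series is in; normalized intensity is the intended scale). Flags are
#' dilated by `t_mask_s` on each side, sample-inclusive.
#'
#' @param x Signal vector.
#' @param fs Sampling rate, Hz.
#' @param std_thresh Change threshold in noise-sd units (default 10).
#' @param amp_thresh Absolute excursion threshold (default 5).
#' @param t_mask_s Dilation half-width, seconds (default 0.5).
#' @param window_s Evaluation window, seconds (default 0.5).
#' @return Logical mask, TRUE = artifactual, same length as `x`.
#' @export
detect_motion_artifacts <- function(x, fs, std_thresh = 10, amp_thresh = 5,
                                    t_mask_s = 0.5, window_s = 0.5) {
  stopifnot(fs > 0)
  n <- length(x)
  w <- max(1L, round(window_s * fs))
  if (n <= w) stop("series shorter than the evaluation window")
  noise_sd <- stats::mad(diff(x))
  flag <- logical(n)
  for (i in seq_len(n - w)) {
    seg <- x[i:(i + w)]
    ptp <- max(seg) - min(seg)
    if ((noise_sd > 0 && ptp > std_thresh * noise_sd) || ptp > amp_thresh)
      flag[i:(i + w)] <- TRUE
  }
  d <- round(t_mask_s * fs)
  if (d > 0 && any(flag)) {
    idx <- which(flag)
    lo <- pmax(idx - d, 1L); hi <- pmin(idx + d, n)
    out <- logical(n)
    for (j in seq_along(idx)) out[lo[j]:hi[j]] <- TRUE
    flag <- out
  }
  flag
}

#' Channel and session rejection rules
#'
#' Applied in order: (1) a channel is rejected when strictly more than
#' `channel_fraction` of its samples are masked as artifactual; (2) when
#' strictly more than `session_fraction` of a participant's channels are
#' bad, the session's channel-pair data are excluded.
#'
#' @param masks Named list (by channel id) of logical artifact masks.
#' @param session Optional data frame `participant`, `channel_id` describing
#'   the session roster; `NULL` applies only the channel rule.
#' @param channel_fraction Contamination threshold (default 0.05).
#' @param session_fraction Bad-channel threshold per participant (default
#'   0.30).
#' @return List `rejected_channels`, `excluded_participants`, and `log`
#'   (data frame of per-channel contaminated fractions).
#' @export
apply_rejection_rules <- function(masks, session = NULL,
                                  channel_fraction = 0.05,
                                  session_fraction = 0.30) {
  frac <- vapply(masks, mean, 0)
  rejected <- as.integer(names(masks)[frac > channel_fraction])
  excluded <- integer()
  if (!is.null(session)) {
    for (p in unique(session$participant)) {
      ch <- session$channel_id[session$participant == p]
      if (mean(ch %in% rejected) > session_fraction)
        excluded <- c(excluded, p)
    }
  }
  list(rejected_channels = rejected, excluded_participants = excluded,
       log = data.frame(channel_id = as.integer(names(masks)),
                        contaminated_fraction = unname(frac)))
}

#' Zero-phase Butterworth band-pass filter
#'
#' Order-3 Butterworth applied forward and backward (`signal::filtfilt`),
#' removing both DC/drift below `low_hz` and cardiac/respiratory components
#' above `high_hz`. Default band 0.01-0.2 Hz.
#'
#' @param x Signal vector.
#' @param fs Sampling rate, Hz; must exceed `2 * high_hz`.
#' @param low_hz,high_hz Band edges, Hz.
#' @param order Filter order (default 3).
#' @return Filtered signal, same length.
#' @export
bandpass_filter <- function(x, fs, low_hz = 0.01, high_hz = 0.2, order = 3) {
  if (fs <= 2 * high_hz)
    stop("sampling rate must exceed twice the upper cutoff")
  bf <- signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
  # remove the mean first: the stop band rejects DC anyway, and a large DC
  # step at the record edges would otherwise ring through the narrow
  # low-frequency corner
  as.numeric(signal::filtfilt(bf, x - mean(x)))
}

#' Optical-density change relative to a baseline window
#'
#' `dOD(t) = -log10(I(t) / I0)` with `I0` the mean intensity over the
#' baseline window.
#'
#' @param x Intensity series (strictly positive).
#' @param baseline Index vector (or logical mask) of the baseline window.
#' @return dOD series.
#' @export
delta_od <- function(x, baseline = seq_along(x)) {
  if (any(x <= 0)) stop("intensities must be strictly positive")
  i0 <- mean(x[baseline])
  if (!is.finite(i0) || i0 <= 0) stop("baseline window empty or non-positive")
  -log10(x / i0)
}

#' Extinction table for the modified Beer-Lambert inversion
#'
#' @param extinction 2 x 2 matrix, rows `HbO`/`HbR`, columns per wavelength,
#'   mm^-1 mM^-1 (decadic).
#' @param dpf Named differential pathlength factor per wavelength.
#' @param pathlength_mm Source-detector separation L, mm.
#' @return An `mbll_table`; errors when the effective matrix is singular or
#'   has condition number above 1e6.
#' @export
mbll_table <- function(extinction = hemoglobin_extinction(),
                       dpf = c("695" = 6, "830" = 6), pathlength_mm = 30) {
  wl <- colnames(extinction)
  stopifnot(length(wl) == 2, all(wl %in% names(dpf)), pathlength_mm > 0)
  m <- t(extinction[c("HbO", "HbR"), wl]) * (pathlength_mm * dpf[wl])
  kappa <- kappa(m, exact = TRUE)
  if (!is.finite(kappa) || kappa > 1e6)
    stop("extinction system ill-conditioned (condition number ",
         format(kappa), ")")
  structure(list(extinction = extinction, dpf = dpf,
                 pathlength_mm = pathlength_mm, m = m,
                 condition_number = kappa),
            class = "mbll_table")
}

#' Modified Beer-Lambert inversion
#'
#' Solves, per sample, the 2 x 2 system
#' `dOD(lambda) = (eps_HbO(lambda) dHbO + eps_HbR(lambda) dHbR) L DPF(lambda)`
#' for the chromophore concentration changes.
#'
#' @param dod_1,dod_2 dOD series at the table's first and second wavelength.
#' @param table An [mbll_table()].
#' @return List `dhbo_mm`, `dhbr_mm` (concentration changes, mM).
#' @export
mbll_invert <- function(dod_1, dod_2, table) {
  stopifnot(inherits(table, "mbll_table"), length(dod_1) == length(dod_2))
  sol <- solve(table$m, rbind(dod_1, dod_2))
  list(dhbo_mm = unname(sol[1, ]), dhbr_mm = unname(sol[2, ]))
}

#' @rdname mbll_invert
#' @param dhbo_mm,dhbr_mm Concentration changes to forward-project.
#' @return `mbll_forward()` returns the matching dOD pair as a 2-row matrix.
#' @export
mbll_forward <- function(dhbo_mm, dhbr_mm, table) {
  stopifnot(inherits(table, "mbll_table"))
  table$m %*% rbind(dhbo_mm, dhbr_mm)
}

#' Oxygen-saturation change from concentration changes
#'
#' `SO2_est(t) = (HbO0 + dHbO) / (tHb0 + dHbO + dHbR)` against known
#' baseline concentrations; `dSO2 = SO2_est - SO2_0`. Estimates are clipped
#' to `[0, 1]` and clip events counted.
#'
#' @param dhbo_mm,dhbr_mm Concentration change series, mM.
#' @param thb0_mm Baseline total hemoglobin, mM (> 0).
#' @param so2_0 Baseline saturation fraction.
#' @return List `so2_est`, `dso2`, `n_clipped`.
#' @export
estimate_so2 <- function(dhbo_mm, dhbr_mm, thb0_mm, so2_0 = 1) {
  stopifnot(thb0_mm > 0, so2_0 >= 0, so2_0 <= 1)
  denom <- thb0_mm + dhbo_mm + dhbr_mm
  if (any(denom <= 0)) stop("total hemoglobin denominator <= 0")
  est <- (so2_0 * thb0_mm + dhbo_mm) / denom
  n_clip <- sum(est < 0 | est > 1)
  est <- pmin(pmax(est, 0), 1)
  list(so2_est = est, dso2 = est - so2_0, n_clipped = n_clip)
}

#' Square-root variance-stabilizing transform
#'
#' Element-wise square root; for Poisson-distributed counts the transformed
#' variance is asymptotically 1/4 regardless of the mean, which linearizes
#' weak-signal attenuation series.
#'
#' @param x Non-negative series.
#' @return `sqrt(x)`.
#' @export
sqrt_transform <- function(x) {
  if (any(x < 0)) stop("values must be >= 0")
  sqrt(x)
}

#' Ordinary least squares with R^2
#'
#' @param x,y Paired observations, n >= 3, `var(x) > 0`.
#' @return List `slope`, `intercept`, `r_squared`.
#' @export
linear_fit_r2 <- function(x, y) {
  if (length(x) < 3 || length(y) != length(x)) stop("need n >= 3 pairs")
  if (stats::var(x) == 0) stop("var(x) is zero")
  f <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(f)[2]),
       intercept = unname(stats::coef(f)[1]),
       r_squared = summary(f)$r.squared)
}

#' Correlation with a normality gate
#'
#' Shapiro-Wilk normality test on both series at level `alpha`; Pearson
#' correlation when both pass, Spearman rank correlation otherwise.
#'
#' @param a,b Equal-length series, n >= 5.
#' @param alpha Normality-test level (default 0.05).
#' @return List `method`, `coefficient`, `p_value`, `normal_a`, `normal_b`.
#' @export
correlate_channels <- function(a, b, alpha = 0.05) {
  stopifnot(length(a) == length(b), length(a) >= 5)
  sw <- function(x) {
    if (stats::sd(x) == 0) return(FALSE)
    stats::shapiro.test(if (length(x) > 5000) x[seq_len(5000)] else x)$p.value > alpha
  }
  na <- sw(a); nb <- sw(b)
  method <- if (na && nb) "pearson" else "spearman"
  ct <- suppressWarnings(stats::cor.test(a, b, method = method, exact = FALSE))
  list(method = method, coefficient = unname(ct$estimate),
       p_value = ct$p.value, normal_a = na, normal_b = nb)
}

#' Full preprocessing chain for one dual-wavelength channel
#'
#' The standard order: motion-artifact masking (masked samples replaced by
#' linear interpolation before filtering so they never shape the filter
#' output, and reported), band-pass filtering of dOD, MBLL inversion.
#'
#' @param i_1,i_2 Intensity series at the table's two wavelengths.
#' @param fs Sampling rate, Hz.
#' @param table An [mbll_table()].
#' @param baseline Baseline-window index vector for [delta_od()].
#' @param filter Apply the 0.01-0.2 Hz band-pass (logical; requires
#'   `fs > 0.4`).
#' @param std_thresh,amp_thresh,t_mask_s Motion-artifact parameters.
#' @return List `dhbo_mm`, `dhbr_mm`, `mask` (combined artifact mask).
#' @export
preprocess_channel <- function(i_1, i_2, fs, table, baseline = seq_len(
                                 max(3, round(30 * fs))),
                               filter = TRUE, std_thresh = 10,
                               amp_thresh = 5, t_mask_s = 0.5) {
  m1 <- detect_motion_artifacts(i_1, fs, std_thresh, amp_thresh, t_mask_s)
  m2 <- detect_motion_artifacts(i_2, fs, std_thresh, amp_thresh, t_mask_s)
  mask <- m1 | m2
  fill <- function(x) {
    if (!any(mask) || all(mask)) return(x)
    x[mask] <- stats::approx(which(!mask), x[!mask], xout = which(mask),
                             rule = 2)$y
    x
  }
  d1 <- delta_od(fill(i_1), baseline)
  d2 <- delta_od(fill(i_2), baseline)
  if (filter) {
    d1 <- bandpass_filter(d1, fs)
    d2 <- bandpass_filter(d2, fs)
  }
  hb <- mbll_invert(d1, d2, table)
  hb$dhbo_mm[mask] <- NA_real_
  hb$dhbr_mm[mask] <- NA_real_
  c(hb, list(mask = mask))
}
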