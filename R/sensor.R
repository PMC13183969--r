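# Physical constants (CODATA 2018, exact SI definitions)
#' Planck constant and speed of light used throughout
#'
#' @return Named list with `h` (J s) and `c` (m/s).
#' @export
physical_constants <- function() {
  list(h = 6.62607015e-34, c = 2.99792458e8)
}

#' sCMOS sensor description
#'
#' Datasheet-level constants of the camera model: geometry, bit depth,
#' read noise `Q` (electrons rms per pixel per readout), conversion gain
#' `CG` (electrons per ADU), per-wavelength quantum efficiency `qe`, and
#' exposure time per TDM slot.
#'
#' @param width,height Sensor size in pixels.
#' @param bit_depth Output bit depth; the ADU ceiling is `2^bit_depth - 1`.
#' @param read_noise_e Read noise, electrons rms.
#' @param conversion_gain Electrons per ADU.
#' @param qe Named numeric vector, quantum efficiency fraction per wavelength
#'   (names are wavelengths in nm).
#' @param exposure_s Exposure time per frame, seconds.
#' @param offset_adu Fixed dark pedestal added to every pixel, ADU. Real
#'   sCMOS cameras add such an offset so read-noise excursions below zero
#'   are not clipped; weak-light MGVs stay unbiased once the pedestal is
#'   subtracted. Default 0.
#' @param shot_noise,quantize Disable Poisson shot noise / ADU rounding for
#'   idealized (noise-free, linear) sensor runs.
#' @return A `sensor_spec` list; `ceiling_adu` is derived.
#' @export
sensor_spec <- function(width = 2048, height = 2048, bit_depth = 12,
                        read_noise_e = 3.57, conversion_gain = 2.33,
                        qe = c("695" = 0.8406, "830" = 0.5333),
                        exposure_s = 0.025, offset_adu = 0,
                        shot_noise = TRUE, quantize = TRUE) {
  stopifnot(conversion_gain > 0, read_noise_e >= 0,
            all(qe > 0), all(qe <= 1), exposure_s > 0, offset_adu >= 0)
  structure(list(width = as.integer(width), height = as.integer(height),
                 bit_depth = as.integer(bit_depth),
                 ceiling_adu = 2L^as.integer(bit_depth) - 1L,
                 read_noise_e = read_noise_e,
                 conversion_gain = conversion_gain,
                 qe = qe, exposure_s = exposure_s, offset_adu = offset_adu,
                 shot_noise = shot_noise, quantize = quantize),
            class = "sensor_spec")
}

.qe_at <- function(spec, wavelength_nm) {
  q <- spec$qe[as.character(wavelength_nm)]
  if (any(is.na(q)))
    stop("no quantum-efficiency entry for wavelength ", wavelength_nm, " nm")
  unname(q)
}

#' Light-source description
#'
#' @param wavelengths_nm Operating wavelengths, nm.
#' @param power_mw Optical power per wavelength at the fiber tip, mW.
#' @param fiber_tip_diameter_mm Emitting fiber tip diameter, mm.
#' @return A `source_spec` list.
#' @export
source_spec <- function(wavelengths_nm = c(695, 830), power_mw = 4,
                        fiber_tip_diameter_mm = 3) {
  stopifnot(power_mw >= 0, fiber_tip_diameter_mm > 0)
  structure(list(wavelengths_nm = wavelengths_nm, power_mw = power_mw,
                 fiber_tip_diameter_mm = fiber_tip_diameter_mm),
            class = "source_spec")
}

#' Mean photoelectrons per pixel per exposure
#'
#' Converts optical power incident on a detector fiber into the expected
#' photoelectron count per sensor pixel: `P * t * eta * lambda / (h*c) / N`.
#'
#' @param power_w Optical power at the detector, watts. Vectorized.
#' @param wavelength_nm Wavelength, nm (must have a QE entry in `spec`).
#' @param spec A [sensor_spec()].
#' @param n_pixels Number of pixels the spot is spread over.
#' @return Mean electrons per pixel per exposure.
#' @export
expected_electrons <- function(power_w, wavelength_nm, spec, n_pixels = 1) {
  stopifnot(all(power_w >= 0), n_pixels >= 1)
  k <- physical_constants()
  eta <- .qe_at(spec, wavelength_nm)
  power_w * spec$exposure_s * eta * (wavelength_nm * 1e-9) / (k$h * k$c) / n_pixels
}

#' Sample pixel values in ADU under the photon-transfer noise model
#'
#' The composite sCMOS model: Poisson shot noise on the photoelectron count,
#' additive Gaussian read noise of `read_noise_e` electrons rms, division by
#' the conversion gain, rounding to integer ADU, and clipping to
#' `[0, 2^bit_depth - 1]`.
#'
#' @param mean_electrons Mean photoelectrons per pixel (scalar or vector; one
#'   draw per element).
#' @param spec A [sensor_spec()].
#' @param n Number of draws when `mean_electrons` is scalar.
#' @return Integer-valued numeric vector of ADU.
#' @export
sample_adu <- function(mean_electrons, spec, n = length(mean_electrons)) {
  if (any(mean_electrons < 0)) stop("mean_electrons must be >= 0")
  mu <- if (length(mean_electrons) == 1L) rep(mean_electrons, n) else mean_electrons
  e <- if (isTRUE(spec$shot_noise)) stats::rpois(length(mu), mu) else mu
  if (spec$read_noise_e > 0)
    e <- e + stats::rnorm(length(mu), 0, spec$read_noise_e)
  adu <- e / spec$conversion_gain + spec$offset_adu
  if (isTRUE(spec$quantize)) adu <- round(adu)
  pmin(pmax(adu, 0), spec$ceiling_adu)
}

#' Sample the mean grayscale value of a whole ROI in one draw
#'
#' Aggregated equivalent of drawing every ROI pixel with [sample_adu()] and
#' averaging: the summed photoelectron count is Poisson with mean
#' `n_pixels * mean_electrons` and the summed read noise is Gaussian with sd
#' `read_noise_e * sqrt(n_pixels)`. Per-pixel quantization adds variance
#' 1/(12 n) ADU^2 to the mean, negligible for speckle-spot ROI sizes; the
#' aggregate is clipped at `n * ceiling`. Used by protocol runners where
#' only the ROI mean matters.
#'
#' @param mean_electrons Mean photoelectrons per pixel.
#' @param n_pixels ROI pixel count.
#' @param spec A [sensor_spec()].
#' @param n Number of MGV draws.
#' @return Numeric vector of MGV in ADU.
#' @export
roi_mgv_sample <- function(mean_electrons, n_pixels, spec, n = 1) {
  stopifnot(mean_electrons >= 0, n_pixels >= 1)
  s <- if (isTRUE(spec$shot_noise))
    stats::rpois(n, n_pixels * mean_electrons)
  else rep(n_pixels * mean_electrons, n)
  if (spec$read_noise_e > 0)
    s <- s + stats::rnorm(n, 0, spec$read_noise_e * sqrt(n_pixels))
  mgv <- s / spec$conversion_gain / n_pixels + spec$offset_adu
  pmin(pmax(mgv, 0), spec$ceiling_adu)
}

#' Lay out speckle spots on the sensor plane
#'
#' Places one circular spot per (detector, wavelength) pair: spots of one
#' wavelength occupy the left half of the sensor, the other wavelength the
#' right half (the two spectral bands are split optically onto the two
#' halves). Spots are packed on a square lattice and must not overlap.
#'
#' @param n_detectors Number of detectors.
#' @param spec A [sensor_spec()].
#' @param radius_px Spot/ROI radius in pixels (default 102).
#' @param wavelengths_nm The two wavelengths.
#' @return A `spot_layout`: data.frame with `detector_id`, `wavelength_nm`,
#'   `cx`, `cy` (0-based pixel centre coordinates), `radius_px`; sensor
#'   dimensions kept as attributes.
#' @export
spot_layout <- function(n_detectors, spec = sensor_spec(), radius_px = 102,
                        wavelengths_nm = c(695, 830)) {
  stopifnot(n_detectors >= 1, radius_px > 0, length(wavelengths_nm) == 2)
  half_w <- spec$width %/% 2
  n_side <- ceiling(sqrt(n_detectors))
  pitch_x <- half_w / n_side
  pitch_y <- spec$height / n_side
  if (min(pitch_x, pitch_y) < 2 * radius_px + 1)
    stop("spots of radius ", radius_px, " cannot be packed without overlap on this sensor")
  rows <- list()
  for (w in seq_along(wavelengths_nm)) {
    x0 <- (w - 1L) * half_w
    for (d in seq_len(n_detectors)) {
      gx <- (d - 1L) %% n_side
      gy <- (d - 1L) %/% n_side
      rows[[length(rows) + 1L]] <- data.frame(
        detector_id = d, wavelength_nm = wavelengths_nm[w],
        cx = x0 + (gx + 0.5) * pitch_x, cy = (gy + 0.5) * pitch_y,
        radius_px = radius_px)
    }
  }
  out <- do.call(rbind, rows)
  if (any(out$cx - radius_px < 0 | out$cx + radius_px > spec$width - 1 |
          out$cy - radius_px < 0 | out$cy + radius_px > spec$height - 1))
    stop("spot layout exceeds sensor bounds")
  attr(out, "sensor") <- spec
  # disc pixels are reused for every frame; compute once
  attr(out, "discs") <- lapply(seq_len(nrow(out)), function(i)
    .disc_pixels(out$cx[i], out$cy[i], out$radius_px[i]))
  class(out) <- c("spot_layout", "data.frame")
  out
}

# 0-based pixel-centre coordinates inside a disc: pixels whose centres lie
# within radius of (cx, cy); returns a 2-column matrix (x, y)
.disc_pixels <- function(cx, cy, radius) {
  xs <- seq(floor(cx - radius), ceiling(cx + radius))
  ys <- seq(floor(cy - radius), ceiling(cy + radius))
  gx <- rep(xs, times = length(ys))
  gy <- rep(ys, each = length(xs))
  keep <- (gx - cx)^2 + (gy - cy)^2 <= radius^2
  cbind(x = gx[keep], y = gy[keep])
}

#' Number of pixels in a disc ROI
#'
#' Discrete count of pixels whose centres lie within `radius` of the centre.
#' At radius 102 this is 32681 pixels, agreeing with the area formula
#' `pi * 102^2 = 32685.1` to within 0.02%; the discrete count is the
#' convention used everywhere in this package.
#'
#' @param radius_px ROI radius in pixels.
#' @return Integer pixel count.
#' @export
roi_pixel_count <- function(radius_px) {
  nrow(.disc_pixels(0, 0, radius_px))
}

#' Render one TDM frame
#'
#' Draws every spot of the layout: spots with an entry in `powers_w` receive
#' shot plus read noise from their flux; all other spots carry read noise
#' only. By default (`full = FALSE`) only pixels inside spot discs are
#' materialized (stored as per-spot patches) since the inter-spot background
#' never enters an ROI; `full = TRUE` renders the complete sensor matrix with
#' read-noise background, for small sensors.
#'
#' @param layout A [spot_layout()].
#' @param powers_w Data frame with `detector_id`, `wavelength_nm`, `power_w`:
#'   optical power reaching each lit spot this slot.
#' @param spec A [sensor_spec()].
#' @param slot TDM slot index (stored on the frame).
#' @param group Active group index (stored on the frame).
#' @param timestamp_s Frame timestamp, seconds.
#' @param full Render the full sensor matrix (logical).
#' @return A `twin_frame`: list with either `adu` (matrix, `full = TRUE`) or
#'   `patches` (list per spot with pixel coordinates and ADU values), plus
#'   `width`, `height`, `timestamp_s`, `slot`, `group`.
#' @export
render_frame <- function(layout, powers_w, spec = attr(layout, "sensor"),
                         slot = 1L, group = 1L, timestamp_s = 0, full = FALSE) {
  stopifnot(inherits(layout, "spot_layout"))
  key <- paste(layout$detector_id, layout$wavelength_nm)
  pkey <- paste(powers_w$detector_id, powers_w$wavelength_nm)
  if (anyDuplicated(pkey)) stop("duplicate (detector, wavelength) in powers_w")
  if (!all(pkey %in% key)) stop("powers_w refers to spots absent from the layout")
  discs <- attr(layout, "discs")
  patches <- vector("list", nrow(layout))
  for (i in seq_len(nrow(layout))) {
    px <- if (!is.null(discs)) discs[[i]] else
      .disc_pixels(layout$cx[i], layout$cy[i], layout$radius_px[i])
    j <- match(key[i], pkey)
    mu <- if (is.na(j)) 0 else {
      p <- powers_w$power_w[j]
      if (p < 0) stop("negative optical power")
      expected_electrons(p, layout$wavelength_nm[i], spec, nrow(px))
    }
    patches[[i]] <- list(detector_id = layout$detector_id[i],
                         wavelength_nm = layout$wavelength_nm[i],
                         pixels = px,
                         adu = sample_adu(mu, spec, n = nrow(px)))
  }
  fr <- list(width = spec$width, height = spec$height,
             timestamp_s = timestamp_s, slot = as.integer(slot),
             group = as.integer(group), patches = patches)
  if (full) {
    m <- matrix(pmin(pmax(round(
      stats::rnorm(spec$width * spec$height, 0, spec$read_noise_e) /
        spec$conversion_gain), 0), spec$ceiling_adu),
      nrow = spec$height, ncol = spec$width)
    for (p in patches) m[cbind(p$pixels[, "y"] + 1L, p$pixels[, "x"] + 1L)] <- p$adu
    fr$adu <- m
    fr$patches <- NULL
  }
  class(fr) <- "twin_frame"
  fr
}

#' Simulate a TDM frame stream
#'
#' Produces one frame per on-slot of the schedule. In slot `g` of cycle `k`,
#' the sources of group `g` are lit; each detector spot receives the summed
#' power of the active sources adjacent to it (at most one for a valid
#' grouping), per wavelength.
#'
#' @param schedule A [build_tdm_schedule()] schedule.
#' @param map The matching [enumerate_channels()] channel map.
#' @param power_fun Function `(time_s, channel_id, wavelength_nm) -> power_w`
#'   giving the optical power a channel delivers to its detector at a given
#'   time. Vectorized over channels.
#' @param layout A [spot_layout()] covering the grid's detectors.
#' @param spec A [sensor_spec()].
#' @param duration_s Simulated duration, seconds.
#' @param wavelengths_nm The two wavelengths.
#' @param on_frame Optional callback `function(frame)` invoked per frame; when
#'   supplied, frames are not accumulated (streaming mode) and the callback's
#'   side effects are the output.
#' @param full Passed to [render_frame()].
#' @return List of `twin_frame` objects (invisible `NULL` in streaming mode).
#' @export
simulate_stream <- function(schedule, map, power_fun, layout,
                            spec = attr(layout, "sensor"), duration_s = 1,
                            wavelengths_nm = c(695, 830),
                            on_frame = NULL, full = FALSE) {
  stopifnot(inherits(schedule, "tdm_schedule"), inherits(map, "channel_map"))
  g1 <- schedule$grid; g2 <- attr(map, "grid")
  if (g1$rows != g2$rows || g1$cols != g2$cols || any(g1$roles != g2$roles))
    stop("schedule and channel map refer to different grids")
  n_cycles <- floor(duration_s * 1000 / schedule$cycle_ms)
  frames <- if (is.null(on_frame)) vector("list", n_cycles * schedule$n_groups)
  fi <- 0L
  for (k in seq_len(n_cycles)) {
    for (g in seq_len(schedule$n_groups)) {
      t_s <- ((k - 1) * schedule$cycle_ms +
                (g - 1) * (schedule$on_ms + schedule$off_ms)) / 1000
      active <- which(schedule$group_of_source == g)
      sel <- map$source_id %in% active
      pw <- NULL
      if (any(sel)) {
        ch <- map[sel, ]
        pw <- do.call(rbind, lapply(wavelengths_nm, function(w) {
          data.frame(detector_id = ch$detector_id, wavelength_nm = w,
                     power_w = power_fun(t_s, ch$channel_id, w))
        }))
        # a valid grouping yields one active source per detector; sum defensively
        pw <- stats::aggregate(power_w ~ detector_id + wavelength_nm, pw, sum)
      } else {
        pw <- data.frame(detector_id = integer(), wavelength_nm = numeric(),
                         power_w = numeric())
      }
      fr <- render_frame(layout, pw, spec, slot = g, group = g,
                         timestamp_s = t_s, full = full)
      fi <- fi + 1L
      if (is.null(on_frame)) frames[[fi]] <- fr else on_frame(fr)
    }
  }
  if (is.null(on_frame)) frames else invisible(NULL)
}

#' Fiber-tip irradiance
#'
#' `P / (pi (d/2)^2)` converted to mW/cm^2: 4 mW over a 3 mm tip gives
#' 56.6 mW/cm^2.
#'
#' @param spec A [source_spec()].
#' @return Irradiance in mW/cm^2 (per wavelength).
#' @export
source_irradiance <- function(spec = source_spec()) {
  if (spec$fiber_tip_diameter_mm <= 0) stop("fiber tip diameter must be > 0")
  r_cm <- spec$fiber_tip_diameter_mm / 2 / 10
  spec$power_mw / (pi * r_cm^2)
}

#' Maximum permissible skin exposure (CW)
#'
#' ANSI Z136.1 continuous-wave skin MPE: `200 * C_A` mW/cm^2 with
#' `C_A = 1` for wavelengths up to 700 nm and
#' `C_A = 10^(2 (lambda_um - 0.700))` from 700 to 1050 nm
#' (200 mW/cm^2 at 695 nm, 363.94 mW/cm^2 at 830 nm).
#'
#' @param wavelength_nm Wavelength in nm, 400-1400.
#' @return MPE in mW/cm^2.
#' @export
mpe_skin <- function(wavelength_nm) {
  if (any(wavelength_nm < 400 | wavelength_nm > 1400))
    stop("wavelength outside the 400-1400 nm band")
  ca <- ifelse(wavelength_nm <= 700, 1,
               ifelse(wavelength_nm <= 1050,
                      10^(2 * (wavelength_nm / 1000 - 0.700)),
                      5))
  200 * ca
}
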