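#' Circular region-of-interest specification
#'
#' @param cx,cy Centre, 0-based pixel coordinates (x right, y down).
#' @param radius_px Radius in pixels (default 102).
#' @param wavelength_nm,detector_id Identity of the spot the ROI reads.
#' @return An `roi_spec` list.
#' @export
roi_spec <- function(cx, cy, radius_px = 102, wavelength_nm = NA,
                     detector_id = NA) {
  stopifnot(radius_px > 0)
  structure(list(cx = cx, cy = cy, radius_px = radius_px,
                 wavelength_nm = wavelength_nm, detector_id = detector_id),
            class = "roi_spec")
}

#' ROIs matching a spot layout
#'
#' One ROI per (detector, wavelength) spot, centred on the spot.
#'
#' @param layout A [spot_layout()].
#' @return List of [roi_spec()] objects.
#' @export
rois_from_layout <- function(layout) {
  stopifnot(inherits(layout, "spot_layout"))
  lapply(seq_len(nrow(layout)), function(i)
    roi_spec(layout$cx[i], layout$cy[i], layout$radius_px[i],
             layout$wavelength_nm[i], layout$detector_id[i]))
}

#' Mean grayscale value of an ROI
#'
#' Arithmetic mean of ADU over pixels whose centres lie within the ROI
#' radius of its centre (Euclidean distance). Works on both full-matrix and
#' patch-rendered frames; for patch frames the ROI must coincide with a
#' rendered spot.
#'
#' @param frame A `twin_frame` from [render_frame()].
#' @param roi An [roi_spec()].
#' @return MGV in ADU.
#' @export
mean_gray_value <- function(frame, roi) {
  stopifnot(inherits(roi, "roi_spec"))
  if (roi$cx - roi$radius_px < 0 || roi$cx + roi$radius_px > frame$width - 1 ||
      roi$cy - roi$radius_px < 0 || roi$cy + roi$radius_px > frame$height - 1)
    stop("ROI extends beyond the frame bounds")
  if (!is.null(frame$adu)) {
    px <- .disc_pixels(roi$cx, roi$cy, roi$radius_px)
    return(mean(frame$adu[cbind(px[, "y"] + 1L, px[, "x"] + 1L)]))
  }
  for (p in frame$patches) {
    ctr <- colMeans(p$pixels)
    if (abs(ctr["x"] - roi$cx) < 0.5 && abs(ctr["y"] - roi$cy) < 0.5) {
      d2 <- (p$pixels[, "x"] - roi$cx)^2 + (p$pixels[, "y"] - roi$cy)^2
      keep <- d2 <= roi$radius_px^2
      return(mean(p$adu[keep]))
    }
  }
  stop("ROI does not coincide with any rendered spot patch")
}

#' Demultiplex a TDM frame stream into channel time series
#'
#' For channel (s, d) the sample of cycle k is the MGV of detector d's ROI
#' in the slot of cycle k where source s's group was active. Missing frames
#' yield NA samples (never interpolated). One series per channel and
#' wavelength, sampled at the schedule rate.
#'
#' @param frames List of `twin_frame` objects in acquisition order (or a
#'   `demux_accumulator`, see [demux_accumulator()]).
#' @param schedule The [build_tdm_schedule()] schedule used in acquisition.
#' @param map The [enumerate_channels()] channel map.
#' @param rois List of [roi_spec()] with `detector_id`/`wavelength_nm` set.
#' @return A `channel_series` data.frame: `time_s`, `channel_id`,
#'   `wavelength_nm`, `mgv`, `saturated` (logical, sample at the ADU
#'   ceiling); attributes `sampling_rate_hz` and `ceiling_adu`.
#' @export
demultiplex <- function(frames, schedule, map, rois) {
  stopifnot(inherits(schedule, "tdm_schedule"), inherits(map, "channel_map"))
  ceiling_adu <- 2L^12 - 1L
  roi_key <- vapply(rois, function(r) paste(r$detector_id, r$wavelength_nm), "")
  wl <- unique(vapply(rois, function(r) r$wavelength_nm, 0))
  n_cycles <- length(frames) %/% schedule$n_groups
  rows <- vector("list", n_cycles * nrow(map) * length(wl))
  ri <- 0L
  for (k in seq_len(n_cycles)) {
    cyc <- frames[((k - 1) * schedule$n_groups + 1):(k * schedule$n_groups)]
    grp_of_frame <- vapply(cyc, function(f) if (is.null(f)) NA_integer_ else f$group, 0L)
    t_k <- (k - 1) * schedule$cycle_ms / 1000
    for (ci in seq_len(nrow(map))) {
      g <- schedule$group_of_source[map$source_id[ci]]
      fi <- match(g, grp_of_frame)
      for (w in wl) {
        ri <- ri + 1L
        if (is.na(fi)) {
          rows[[ri]] <- data.frame(time_s = t_k, channel_id = map$channel_id[ci],
                                   wavelength_nm = w, mgv = NA_real_,
                                   saturated = NA)
          next
        }
        j <- match(paste(map$detector_id[ci], w), roi_key)
        if (is.na(j)) stop("no ROI for detector ", map$detector_id[ci],
                           " at ", w, " nm")
        v <- mean_gray_value(cyc[[fi]], rois[[j]])
        rows[[ri]] <- data.frame(time_s = t_k, channel_id = map$channel_id[ci],
                                 wavelength_nm = w, mgv = v,
                                 saturated = v >= ceiling_adu)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "sampling_rate_hz") <- schedule$sampling_rate_hz
  attr(out, "ceiling_adu") <- ceiling_adu
  class(out) <- c("channel_series", "data.frame")
  out
}

#' Streaming demultiplexer
#'
#' Builds the per-frame callback form of [demultiplex()] so frame streams
#' need never be held in memory: pass `acc$on_frame` to [simulate_stream()],
#' then read `acc$series()`.
#'
#' @inheritParams demultiplex
#' @return List with `on_frame` (callback) and `series()` (retrieves the
#'   accumulated `channel_series`).
#' @export
demux_accumulator <- function(schedule, map, rois) {
  env <- new.env(parent = emptyenv())
  env$rows <- list()
  roi_key <- vapply(rois, function(r) paste(r$detector_id, r$wavelength_nm), "")
  wl <- unique(vapply(rois, function(r) r$wavelength_nm, 0))
  ceiling_adu <- 2L^12 - 1L
  on_frame <- function(frame) {
    g <- frame$group
    sel <- which(schedule$group_of_source[map$source_id] == g)
    for (ci in sel) for (w in wl) {
      j <- match(paste(map$detector_id[ci], w), roi_key)
      v <- mean_gray_value(frame, rois[[j]])
      env$rows[[length(env$rows) + 1L]] <-
        data.frame(time_s = frame$timestamp_s -
                     (g - 1) * (schedule$on_ms + schedule$off_ms) / 1000,
                   channel_id = map$channel_id[ci], wavelength_nm = w,
                   mgv = v, saturated = v >= ceiling_adu)
    }
  }
  series <- function() {
    out <- do.call(rbind, env$rows)
    out <- out[order(out$channel_id, out$wavelength_nm, out$time_s), ]
    rownames(out) <- NULL
    attr(out, "sampling_rate_hz") <- schedule$sampling_rate_hz
    attr(out, "ceiling_adu") <- ceiling_adu
    class(out) <- c("channel_series", "data.frame")
    out
  }
  list(on_frame = on_frame, series = series)
}

#' Normalize channel series by emitter power
#'
#' Divides each channel's values by its source's measured emission power,
#' removing emitter-to-emitter intensity differences; the result is
#' invariant to a global rescaling of all powers up to one common factor.
#'
#' @param series A `channel_series`.
#' @param map The channel map linking channels to sources.
#' @param source_powers_mw Numeric vector indexed by source id, mW.
#' @return The series with `mgv` replaced by normalized intensity (column
#'   renamed `value`).
#' @export
normalize_by_source <- function(series, map, source_powers_mw) {
  stopifnot(inherits(series, "channel_series"))
  src <- map$source_id[match(series$channel_id, map$channel_id)]
  p <- source_powers_mw[src]
  if (any(is.na(p)) || any(p <= 0))
    stop("every channel's source needs a power entry > 0")
  out <- series
  out$value <- out$mgv / p
  out$mgv <- NULL
  out
}

#' Flag saturated samples
#'
#' @param series A `channel_series` in the ADU domain.
#' @param warn_fraction Channel-level warning threshold on the flagged
#'   fraction (default 0.1%).
#' @return The series with a refreshed `saturated` column; warns per channel
#'   exceeding `warn_fraction`.
#' @export
flag_saturation <- function(series, warn_fraction = 0.001) {
  stopifnot(inherits(series, "channel_series"))
  ceiling_adu <- attr(series, "ceiling_adu")
  series$saturated <- series$mgv >= ceiling_adu
  frac <- tapply(series$saturated, series$channel_id, mean)
  bad <- names(frac)[frac > warn_fraction]
  if (length(bad))
    warning("saturation above ", 100 * warn_fraction, "% on channel(s) ",
            paste(bad, collapse = ", "))
  series
}
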