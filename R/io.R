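#' Write / read a frame stack as multi-page 16-bit TIFF with a JSON sidecar
#'
#' Frames are stored full-frame (patch frames are materialized with zero
#' background); the sidecar records the acquisition metadata needed to
#' demultiplex later (schedule, layout, seed).
#'
#' @param frames List of `twin_frame` objects.
#' @param path Output `.tiff` path; the sidecar goes to `paste0(path,
#'   ".json")`.
#' @param schedule,layout,seed Metadata for the sidecar (optional).
#' @return `path`, invisibly.
#' @export
write_frames_tiff <- function(frames, path, schedule = NULL, layout = NULL,
                              seed = NULL) {
  mats <- lapply(frames, function(f) {
    m <- if (!is.null(f$adu)) f$adu else {
      m0 <- matrix(0, f$height, f$width)
      for (p in f$patches)
        m0[cbind(p$pixels[, "y"] + 1L, p$pixels[, "x"] + 1L)] <- p$adu
      m0
    }
    m / 65535  # tiff package expects [0,1]; 16-bit container
  })
  tiff::writeTIFF(mats, path, bits.per.sample = 16L, compression = "none")
  meta <- list(
    n_frames = length(frames),
    timestamps_s = vapply(frames, `[[`, 0, "timestamp_s"),
    slots = vapply(frames, `[[`, 0L, "slot"),
    groups = vapply(frames, `[[`, 0L, "group"),
    seed = seed)
  if (!is.null(schedule)) meta$geometry <- geometry_config(schedule)
  if (!is.null(layout))
    meta$layout <- as.list(as.data.frame(unclass(layout))[
      c("detector_id", "wavelength_nm", "cx", "cy", "radius_px")])
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_frames_tiff
#' @return `read_frames_tiff()` returns the frame list (full-matrix frames)
#'   with metadata attached as attribute `meta`.
#' @export
read_frames_tiff <- function(path) {
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar,
                                                        simplifyVector = TRUE)
  mats <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(mats)) mats <- list(mats)
  frames <- lapply(seq_along(mats), function(i) {
    structure(list(width = ncol(mats[[i]]), height = nrow(mats[[i]]),
                   timestamp_s = if (!is.null(meta)) meta$timestamps_s[i] else NA,
                   slot = if (!is.null(meta)) meta$slots[i] else i,
                   group = if (!is.null(meta)) meta$groups[i] else i,
                   adu = mats[[i]]),
              class = "twin_frame")
  })
  attr(frames, "meta") <- meta
  frames
}

#' Channel-series CSV interchange
#'
#' Columns `time_s`, `channel_id`, `wavelength_nm`, `mgv` (or `value`),
#' `saturated`.
#'
#' @param series A `channel_series` data frame.
#' @param path CSV path.
#' @return `path` / the series, invisibly for the writer.
#' @export
write_series_csv <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series_csv
#' @param sampling_rate_hz Sampling rate restored onto the object.
#' @export
read_series_csv <- function(path, sampling_rate_hz = NULL) {
  out <- utils::read.csv(path)
  need <- c("time_s", "channel_id", "wavelength_nm")
  if (!all(need %in% names(out)))
    stop("malformed channel-series CSV ", path, ": missing column(s) ",
         paste(setdiff(need, names(out)), collapse = ", "))
  if (is.null(sampling_rate_hz)) {
    ts <- sort(unique(out$time_s))
    sampling_rate_hz <- if (length(ts) > 1) 1 / stats::median(diff(ts)) else NA
  }
  attr(out, "sampling_rate_hz") <- sampling_rate_hz
  attr(out, "ceiling_adu") <- 2L^12 - 1L
  class(out) <- c("channel_series", "data.frame")
  out
}

#' Write a QC or statistics report as JSON
#'
#' @param report A `qc_report` or any list of results.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  if (inherits(report, "qc_report")) {
    report <- list(snr_db = report$snr,
                   snr_summary = as.list(report$snr_summary),
                   nep_theoretical_w = lapply(report$nep_theoretical,
                                              function(x) x),
                   dor_db = as.list(report$dor_db),
                   drift = if (!is.null(report$drift))
                     list(linear_rate_pct_h = report$drift$linear_rate_pct_h,
                          sigma3_pct = report$drift$sigma3_pct,
                          allan = report$drift$allan))
  }
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

# ---- run configuration -----------------------------------------------------

.config_schema <- list(
  geometry = c("rows", "cols", "pitch_mm", "corner_role", "n_groups",
               "on_ms", "off_ms", "group_of_source"),
  sensor = c("width", "height", "bit_depth", "read_noise_e",
             "conversion_gain", "qe", "exposure_s"),
  experiment = c("kind", "duration_s", "preset", "n_steps", "musp",
                 "coupling", "state_a_mgv", "linear_rate_pct_h",
                 "white_sd", "n_reference_samples"),
  pipeline = c("std_thresh", "amp_thresh", "t_mask_s", "low_hz", "high_hz",
               "dpf", "pathlength_mm"),
  seed = NULL, out_dir = NULL, log_level = NULL)

#' Read and validate a run configuration
#'
#' YAML file with blocks `geometry`, `sensor`, `experiment`, `pipeline` and
#' scalar keys `seed`, `out_dir`, `log_level`. Unknown keys are rejected
#' with a diagnostic naming the offender. Every run should write its
#' resolved configuration next to its outputs ([write_run_config()]).
#'
#' @param path YAML config path.
#' @return Validated named list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), names(.config_schema))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (blk in names(cfg)) {
    allowed <- .config_schema[[blk]]
    if (is.null(allowed)) next
    bad <- setdiff(names(cfg[[blk]]), allowed)
    if (length(bad))
      stop("unknown key(s) in '", blk, "': ", paste(bad, collapse = ", "))
  }
  cfg
}

#' @rdname read_run_config
#' @param cfg Config list.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Deterministic named sub-seeds from one global seed
#'
#' Fans a single run seed out to independent component seeds (sensor,
#' phantom, artifacts, ...) so stages stay reproducible when run separately.
#' Sub-seeds are derived by hashing the component name onto the seed and
#' kept below 2^31.
#'
#' @param seed Global integer seed.
#' @param component Component name.
#' @return Integer sub-seed.
#' @export
sub_seed <- function(seed, component) {
  h <- sum(utf8ToInt(component) * seq_along(utf8ToInt(component)))
  as.integer((as.double(seed) * 7919 + h * 104729) %% 2147483647)
}
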