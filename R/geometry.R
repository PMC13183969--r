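#' Construct a checkerboard optode grid
#'
#' Builds a rectangular optode array in which sources and detectors alternate
#' in a checkerboard pattern, the montage used by time-division-multiplexed
#' continuous-wave fNIRS arrays. With `corner_role = "source"` the four grid
#' corners are sources, so a 3 x 11 grid carries 17 sources and 16 detectors.
#'
#' @param rows,cols Grid dimensions (positive integers).
#' @param pitch_mm Source-detector separation between orthogonal neighbours,
#'   in millimetres. Default 30 mm.
#' @param corner_role Role placed on the (1,1) corner, `"source"` (default)
#'   or `"detector"`.
#' @return An object of class `optode_grid`: a list with `rows`, `cols`,
#'   `pitch_mm`, a `rows x cols` character matrix `roles`, integer matrices
#'   `ids` (role-local 1-based ids laid out row-major), and the counts
#'   `n_sources`, `n_detectors`.
#' @examples
#' g <- build_grid(3, 11, 30)
#' g$n_sources    # 17
#' g$n_detectors  # 16
#' @export
build_grid <- function(rows, cols, pitch_mm = 30, corner_role = c("source", "detector")) {
  corner_role <- match.arg(corner_role)
  if (length(rows) != 1L || length(cols) != 1L || rows < 1 || cols < 1 ||
      rows != round(rows) || cols != round(cols))
    stop("rows and cols must be positive integers")
  if (!is.numeric(pitch_mm) || pitch_mm <= 0) stop("pitch_mm must be > 0")

  parity <- outer(seq_len(rows), seq_len(cols), `+`) %% 2L
  # (1,1) has parity 0; assign corner_role to parity-0 nodes
  roles <- matrix(ifelse(parity == 0L, corner_role,
                         if (corner_role == "source") "detector" else "source"),
                  rows, cols)
  ids <- matrix(0L, rows, cols)  # role-local ids, row-major
  sid <- did <- 0L
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    if (roles[r, c] == "source") { sid <- sid + 1L; ids[r, c] <- sid }
    else { did <- did + 1L; ids[r, c] <- did }
  }
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 pitch_mm = pitch_mm, roles = roles, ids = ids,
                 n_sources = sid, n_detectors = did),
            class = "optode_grid")
}

#' @export
print.optode_grid <- function(x, ...) {
  cat(sprintf("optode_grid: %d x %d, pitch %g mm, %d sources / %d detectors\n",
              x$rows, x$cols, x$pitch_mm, x$n_sources, x$n_detectors))
  invisible(x)
}

# grid-node coordinates (row, col) of a source / detector id
.node_of <- function(grid, role, id) {
  w <- which(grid$roles == role & grid$ids == id, arr.ind = TRUE)
  if (nrow(w) != 1L) stop("unknown ", role, " id ", id)
  w[1L, ]
}

#' Enumerate source-detector measurement channels
#'
#' A channel is every orthogonally adjacent source-detector pair of the grid;
#' for a checkerboard this is the set of grid-graph edges, so a `rows x cols`
#' grid forms `rows*(cols-1) + (rows-1)*cols` channels (52 on 3 x 11).
#' Ordering is deterministic: row-major by detector node, then row-major by
#' source node; channel ids are 1-based. Published channel numberings of any
#' particular instrument are not guaranteed to coincide with this ordering.
#'
#' @param grid An `optode_grid`.
#' @return A `channel_map`: data.frame with columns `channel_id`, `source_id`,
#'   `detector_id`, `separation_mm`, plus the originating grid as attribute
#'   `grid`.
#' @export
enumerate_channels <- function(grid) {
  stopifnot(inherits(grid, "optode_grid"))
  out <- list()
  k <- 0L
  for (r in seq_len(grid$rows)) for (c in seq_len(grid$cols)) {
    if (grid$roles[r, c] != "detector") next
    did <- grid$ids[r, c]
    for (nb in list(c(r - 1L, c), c(r, c - 1L), c(r, c + 1L), c(r + 1L, c))) {
      if (nb[1] < 1 || nb[1] > grid$rows || nb[2] < 1 || nb[2] > grid$cols) next
      if (grid$roles[nb[1], nb[2]] != "source") next
      k <- k + 1L
      out[[k]] <- data.frame(channel_id = k,
                             source_id = grid$ids[nb[1], nb[2]],
                             detector_id = did,
                             separation_mm = grid$pitch_mm)
    }
  }
  cm <- do.call(rbind, out)
  # reorder sources row-major within each detector block
  ord <- order(cm$detector_id, cm$source_id)
  cm <- cm[ord, ]
  cm$channel_id <- seq_len(nrow(cm))
  rownames(cm) <- NULL
  attr(cm, "grid") <- grid
  class(cm) <- c("channel_map", "data.frame")
  cm
}

# source conflict graph: sources sharing an adjacent detector must not share
# a TDM group, otherwise that detector's ROI mixes two emitters in one slot
.source_conflicts <- function(map) {
  conf <- list()
  for (d in unique(map$detector_id)) {
    s <- sort(unique(map$source_id[map$detector_id == d]))
    if (length(s) >= 2) {
      pr <- utils::combn(s, 2)
      for (j in seq_len(ncol(pr))) conf[[length(conf) + 1L]] <- pr[, j]
    }
  }
  unique(conf)
}

#' Build a time-division-multiplexing schedule
#'
#' Assigns each source to one of `n_groups` activation slots so that no
#' detector is orthogonally adjacent to two sources of the same group
#' (demultiplexing unambiguity). Group assignment is a deterministic greedy
#' colouring of the "shares a detector" source-conflict graph in source-id
#' order. The full cycle lasts `n_groups * (on_ms + off_ms)` and the channel
#' sampling rate is `1000 / cycle_ms` Hz (4 groups of 25 + 25 ms give a
#' 200 ms cycle and 5 Hz).
#'
#' @param grid An `optode_grid`.
#' @param n_groups Number of activation groups (>= 1).
#' @param on_ms,off_ms Source on / off duration per slot, milliseconds.
#' @return A `tdm_schedule`: list with `n_groups`, `on_ms`, `off_ms`,
#'   `group_of_source` (integer vector indexed by source id),
#'   `cycle_ms`, `sampling_rate_hz`, and the `grid`.
#' @export
build_tdm_schedule <- function(grid, n_groups = 4, on_ms = 25, off_ms = 25) {
  stopifnot(inherits(grid, "optode_grid"))
  if (n_groups < 1 || n_groups != round(n_groups)) stop("n_groups must be a positive integer")
  if (on_ms <= 0 || off_ms <= 0) stop("on_ms and off_ms must be > 0")
  map <- enumerate_channels(grid)
  conf <- .source_conflicts(map)
  adj <- vector("list", grid$n_sources)
  for (p in conf) {
    adj[[p[1]]] <- c(adj[[p[1]]], p[2])
    adj[[p[2]]] <- c(adj[[p[2]]], p[1])
  }
  group <- integer(grid$n_sources)
  for (s in seq_len(grid$n_sources)) {
    used <- group[adj[[s]][group[adj[[s]]] > 0L]]
    free <- setdiff(seq_len(n_groups), used)
    if (!length(free)) {
      bad <- adj[[s]][1L]
      det <- intersect(map$detector_id[map$source_id == s],
                       map$detector_id[map$source_id == bad])
      stop(sprintf(
        "infeasible grouping: source %d cannot take any of %d groups (e.g. conflicts with source %d at detector %d)",
        s, n_groups, bad, det[1]))
    }
    group[s] <- min(free)
  }
  cycle_ms <- n_groups * (on_ms + off_ms)
  structure(list(n_groups = as.integer(n_groups), on_ms = on_ms, off_ms = off_ms,
                 group_of_source = group, cycle_ms = cycle_ms,
                 sampling_rate_hz = 1000 / cycle_ms, grid = grid),
            class = "tdm_schedule")
}

#' Validate a TDM grouping against a channel map
#'
#' Checks that no detector is adjacent to two sources assigned the same
#' activation group; such a pair could not be told apart from a single ROI.
#'
#' @param schedule A `tdm_schedule`.
#' @param map A `channel_map` from the same grid.
#' @return A list `valid` (logical) and `conflicts` (data.frame with
#'   `detector_id`, `source_a`, `source_b`, `group`; zero rows if valid).
#' @export
validate_grouping <- function(schedule, map) {
  stopifnot(inherits(schedule, "tdm_schedule"), inherits(map, "channel_map"))
  g1 <- schedule$grid; g2 <- attr(map, "grid")
  if (g1$rows != g2$rows || g1$cols != g2$cols || any(g1$roles != g2$roles))
    stop("schedule and channel map refer to different grids")
  rows <- list()
  for (d in unique(map$detector_id)) {
    s <- sort(unique(map$source_id[map$detector_id == d]))
    if (length(s) < 2) next
    grp <- schedule$group_of_source[s]
    dup <- grp[duplicated(grp)]
    for (gd in unique(dup)) {
      ss <- s[grp == gd]
      pr <- utils::combn(ss, 2)
      for (j in seq_len(ncol(pr)))
        rows[[length(rows) + 1L]] <- data.frame(detector_id = d,
                                                source_a = pr[1, j],
                                                source_b = pr[2, j],
                                                group = gd)
    }
  }
  conflicts <- if (length(rows)) do.call(rbind, rows) else
    data.frame(detector_id = integer(), source_a = integer(),
               source_b = integer(), group = integer())
  list(valid = nrow(conflicts) == 0L, conflicts = conflicts)
}

#' Serialize / restore geometry configuration
#'
#' @param schedule A `tdm_schedule`.
#' @return `geometry_config()` returns a plain named list suitable for YAML
#'   serialization; `geometry_from_config()` rebuilds the grid and schedule.
#' @export
geometry_config <- function(schedule) {
  stopifnot(inherits(schedule, "tdm_schedule"))
  g <- schedule$grid
  list(rows = g$rows, cols = g$cols, pitch_mm = g$pitch_mm,
       corner_role = g$roles[1, 1],
       n_groups = schedule$n_groups, on_ms = schedule$on_ms,
       off_ms = schedule$off_ms,
       group_of_source = as.integer(schedule$group_of_source))
}

#' @rdname geometry_config
#' @param config A list as produced by `geometry_config()`.
#' @export
geometry_from_config <- function(config) {
  g <- build_grid(config$rows, config$cols, config$pitch_mm,
                  corner_role = config$corner_role)
  sch <- build_tdm_schedule(g, config$n_groups, config$on_ms, config$off_ms)
  if (!is.null(config$group_of_source))
    sch$group_of_source <- as.integer(config$group_of_source)
  sch
}
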