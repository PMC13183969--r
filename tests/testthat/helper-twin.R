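# small-scale fixtures used across test files

tiny_sensor <- function(width = 64, height = 64, ...) {
  sensor_spec(width = width, height = height, ...)
}

noiseless_sensor <- function(width = 64, height = 64) {
  sensor_spec(width = width, height = height, read_noise_e = 0,
              shot_noise = FALSE, quantize = FALSE)
}

# brute-force channel enumeration: scan every (node, node) pair
oracle_channel_count <- function(grid) {
  n <- 0L
  for (r1 in seq_len(grid$rows)) for (c1 in seq_len(grid$cols))
    for (r2 in seq_len(grid$rows)) for (c2 in seq_len(grid$cols)) {
      if (abs(r1 - r2) + abs(c1 - c2) != 1L) next
      if (grid$roles[r1, c1] == "source" && grid$roles[r2, c2] == "detector")
        n <- n + 1L
    }
  n
}

# brute-force TDM conflict search over every detector
oracle_has_conflict <- function(grid, map, group_of_source) {
  for (d in unique(map$detector_id)) {
    s <- unique(map$source_id[map$detector_id == d])
    if (anyDuplicated(group_of_source[s])) return(TRUE)
  }
  FALSE
}
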