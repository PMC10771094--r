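# Independent oracles used by the tests; deliberately naive implementations
# kept separate from the package's code paths.

# brute-force O(n^2) neighbor filter: keep detection i iff some detection j
# of the same camera in an adjacent frame lies within radius
brute_force_neighbor <- function(det, radius_px) {
  keep <- logical(nrow(det))
  for (i in seq_len(nrow(det))) {
    for (j in seq_len(nrow(det))) {
      if (i == j) next
      if (det$camera[j] != det$camera[i]) next
      if (abs(det$frame[j] - det$frame[i]) != 1L) next
      d2 <- (det$x_px[i] - det$x_px[j])^2 + (det$y_px[i] - det$y_px[j])^2
      if (d2 <= radius_px^2) { keep[i] <- TRUE; break }
    }
  }
  det[keep, ]
}

# sort-and-interpolate quantile (linear interpolation of order statistics)
quantile_oracle <- function(x, tau) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * tau
  lo <- floor(h)
  if (lo >= n - 1) return(x[n])
  x[lo + 1] + (h - lo) * (x[lo + 2] - x[lo + 1])
}

# desk-scale configuration: short periods so whole trials render and analyze
# in seconds
desk_config <- function(period_s = 8, seed = 1L) {
  cfg <- default_config(seed)
  cfg$schedule$period_s <- period_s
  cfg$stats$q_min <- 10
  cfg$stats$B <- 500
  cfg$cameras$resolution <- c(160L, 120L)
  cfg
}

# small synthetic fused track built directly from given per-period distances
toy_track <- function(bat_id, period_values, fps = 30) {
  labels <- names(period_values)
  rows <- lapply(seq_along(labels), function(i) {
    v <- period_values[[i]]
    tibble::tibble(bat_id = bat_id,
                   frame = seq_along(v) - 1L + (i - 1L) * 10000L,
                   period_label = labels[i], distance_m = v,
                   camera = NA_integer_)
  })
  dplyr::bind_rows(rows)
}
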