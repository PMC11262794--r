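# Independent oracles, kept deliberately naive: plain loops, no reuse of
# package internals.

# Per-pixel loop: count in-well pixels whose absolute change meets the
# threshold. `well` uses 0-based half-open rectangles.
oracle_activity <- function(frame_a, frame_b, well, threshold) {
  count <- 0L
  for (y in (well$y0 + 1L):well$y1) {
    for (x in (well$x0 + 1L):well$x1) {
      if (abs(frame_a[y, x] - frame_b[y, x]) >= threshold) {
        count <- count + 1L
      }
    }
  }
  count
}

# Run-length bout decomposition of a binary asleep vector by explicit scan.
oracle_bouts <- function(asleep, min_len = 1L) {
  starts <- integer(0)
  ends <- integer(0)
  run_start <- NA_integer_
  for (i in seq_along(asleep)) {
    if (asleep[i] && is.na(run_start)) run_start <- i
    closing <- !is.na(run_start) && (!asleep[i] || i == length(asleep))
    if (closing) {
      run_end <- if (asleep[i]) i else i - 1L
      if (run_end - run_start + 1L >= min_len) {
        starts <- c(starts, run_start)
        ends <- c(ends, run_end)
      }
      run_start <- NA_integer_
    }
  }
  data.frame(start = starts, end = ends, len = ends - starts + 1L)
}

# Random 8-bit frame pair of the given size.
random_frame <- function(nr = 16L, nc = 16L) {
  matrix(sample(0:255, nr * nc, replace = TRUE), nrow = nr)
}

# Wrap a bare activity vector as the package's activity_df container.
activity_from_vector <- function(values, well_id = "w1", dt = 6) {
  df <- data.frame(well_id = well_id, interval = seq_along(values),
                   time_s = (seq_along(values) - 1) * dt,
                   activity = values)
  attr(df, "frame_interval_s") <- dt
  class(df) <- c("activity_df", "data.frame")
  df
}
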