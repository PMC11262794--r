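#' Stage-specific gray-scale detection thresholds
#'
#' Frame-differencing uses a binary threshold on per-pixel intensity change
#' chosen to eliminate camera noise: 40 gray-scale units for 2nd-instar
#' larvae and 45 for 3rd instars, whose larger bodies move more pixels.
#'
#' @param stage `"L2"` or `"L3"`.
#' @return The threshold in gray-scale units.
#' @examples
#' default_threshold("L2")  # 40
#' default_threshold("L3")  # 45
#' @export
default_threshold <- function(stage) {
  if (!is.character(stage) || length(stage) != 1L ||
      !stage %in% c("L2", "L3")) {
    stop("`stage` must be \"L2\" or \"L3\"", call. = FALSE)
  }
  c(L2 = 40, L3 = 45)[[stage]]
}

#' Count supra-threshold pixel changes between two frames within a well
#'
#' Temporally adjacent frames are subtracted and the absolute per-pixel
#' intensity change is compared against the binary threshold: changes
#' greater than or equal to the threshold count as "change" (one pixel),
#' smaller changes count as "no change" (zero). Activity is the sum of
#' changed pixels inside the well rectangle.
#'
#' @param frame_a,frame_b grayscale intensity matrices of equal dimensions.
#' @param well rectangle as a list/row with `x0`, `y0`, `x1`, `y1`
#'   (0-based, half-open pixel coordinates).
#' @param threshold gray-scale units (> 0); see [default_threshold()].
#' @return Integer count of changed pixels within the well.
#' @export
frame_pair_activity <- function(frame_a, frame_b, well, threshold) {
  if (!is.matrix(frame_a) || !identical(dim(frame_a), dim(frame_b))) {
    stop("frames must be matrices of identical dimensions", call. = FALSE)
  }
  check_positive(threshold, "threshold")
  x0 <- well$x0; x1 <- well$x1; y0 <- well$y0; y1 <- well$y1
  if (x0 < 0 || y0 < 0 || x1 > ncol(frame_a) || y1 > nrow(frame_a)) {
    stop("well rectangle extends outside the frame", call. = FALSE)
  }
  rows <- (y0 + 1L):y1
  cols <- (x0 + 1L):x1
  # widen to double before subtracting so 8-bit storage cannot wrap
  d <- abs(frame_a[rows, cols, drop = FALSE] -
             frame_b[rows, cols, drop = FALSE])
  sum(d >= threshold)
}

#' Extract per-well activity traces from an image stack
#'
#' Applies [frame_pair_activity()] to every temporally adjacent frame pair
#' and every well. Trace value `i` is the activity between frames `i` and
#' `i + 1`; `time_s` is the start time of the interval, with frame 1 at 0 s.
#'
#' @param stack an [image_stack()].
#' @param layout a [well_layout()].
#' @param threshold gray-scale units; see [default_threshold()].
#' @return A long-format data.frame of class `activity_df` with columns
#'   `well_id`, `interval` (1-based), `time_s`, `activity`, and attributes
#'   `threshold` and `frame_interval_s`.
#' @export
extract_activity <- function(stack, layout, threshold) {
  stopifnot(inherits(stack, "image_stack"))
  if (!inherits(layout, "well_layout")) layout <- well_layout(layout)
  check_positive(threshold, "threshold")
  check_wells_in_frame(layout, dim(stack$frames[[1L]]))
  n_frames <- length(stack$frames)
  n_wells <- nrow(layout)
  n_iv <- n_frames - 1L
  vals <- matrix(0L, nrow = n_iv, ncol = n_wells)
  # precompute index ranges once; diff each frame pair once for all wells
  rows_list <- lapply(seq_len(n_wells),
                      function(w) (layout$y0[w] + 1L):layout$y1[w])
  cols_list <- lapply(seq_len(n_wells),
                      function(w) (layout$x0[w] + 1L):layout$x1[w])
  for (i in seq_len(n_iv)) {
    d <- abs(stack$frames[[i + 1L]] - stack$frames[[i]]) >= threshold
    for (w in seq_len(n_wells)) {
      vals[i, w] <- sum(d[rows_list[[w]], cols_list[[w]]])
    }
  }
  out <- data.frame(
    well_id = rep(layout$well_id, each = n_iv),
    interval = rep(seq_len(n_iv), times = n_wells),
    time_s = rep((seq_len(n_iv) - 1L) * stack$frame_interval_s,
                 times = n_wells),
    activity = as.vector(vals))
  attr(out, "threshold") <- threshold
  attr(out, "frame_interval_s") <- stack$frame_interval_s
  class(out) <- c("activity_df", "data.frame")
  out
}

#' Read and write activity traces as CSV
#'
#' Long format: `well_id`, `interval`, `time_s`, `activity`. The threshold
#' and frame interval ride along as extra constant columns so the CSV is
#' self-describing.
#'
#' @param activity an `activity_df` from [extract_activity()].
#' @param path CSV path.
#' @export
write_activity <- function(activity, path) {
  df <- as.data.frame(activity)
  df$threshold <- attr(activity, "threshold")
  df$frame_interval_s <- attr(activity, "frame_interval_s")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_activity
#' @export
read_activity <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("activity file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well_id", "interval", "time_s", "activity")
  if (!all(need %in% names(df))) {
    stop("activity CSV needs columns well_id, interval, time_s, activity",
         call. = FALSE)
  }
  out <- df[, need]
  attr(out, "threshold") <- if ("threshold" %in% names(df))
    df$threshold[1L] else NA_real_
  attr(out, "frame_interval_s") <- if ("frame_interval_s" %in% names(df))
    df$frame_interval_s[1L] else stop("activity CSV lacks frame_interval_s",
                                      call. = FALSE)
  class(out) <- c("activity_df", "data.frame")
  out
}
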