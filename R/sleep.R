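#' Call sleep and decompose it into bouts
#'
#' Sleep is defined as an activity value of zero between frames: interval
#' `i` is asleep iff `activity[i] == 0`. Bouts are maximal runs of
#' consecutive asleep intervals; each bout's duration is its run length
#' times the frame interval. Runs shorter than `min_bout_intervals` are
#' discarded from the bout list and from sleep totals (the default of one
#' interval keeps every zero-activity interval, the strict reading of the
#' definition).
#'
#' @param activity an `activity_df` from [extract_activity()] (or
#'   [read_activity()]); may contain many wells.
#' @param window optional numeric `c(start_s, end_s)`; only intervals whose
#'   start time lies in `[start_s, end_s)` are analyzed.
#' @param min_bout_intervals minimum run length (in intervals) for a run of
#'   quiescence to count as a sleep bout.
#' @return An object of class `sleep_record`: list with `calls` (data.frame
#'   `well_id`, `interval`, `time_s`, `asleep`, `in_bout`), `bouts`
#'   (data.frame `well_id`, `start_interval`, `end_interval`, `n_intervals`,
#'   `duration_s`), `frame_interval_s`, `window`, `min_bout_intervals`.
#' @examples
#' a <- data.frame(well_id = "w1", interval = 1:5, time_s = 0:4 * 6,
#'                 activity = c(0, 0, 0, 5, 0))
#' attr(a, "frame_interval_s") <- 6
#' rec <- call_sleep(a)
#' rec$bouts  # one 18 s bout and one 6 s bout
#' @export
call_sleep <- function(activity, window = NULL, min_bout_intervals = 1L) {
  dt <- attr(activity, "frame_interval_s")
  if (is.null(dt)) stop("activity lacks a frame_interval_s attribute",
                        call. = FALSE)
  min_bout_intervals <- check_count(min_bout_intervals,
                                    "min_bout_intervals")
  df <- as.data.frame(activity)
  if (!is.null(window)) {
    if (length(window) != 2L || window[2L] <= window[1L]) {
      stop("`window` must be c(start_s, end_s) with end > start",
           call. = FALSE)
    }
    df <- df[df$time_s >= window[1L] & df$time_s < window[2L], , drop = FALSE]
    if (nrow(df) == 0L) {
      stop("window contains no inter-frame intervals", call. = FALSE)
    }
  }
  df <- df[order(df$well_id, df$interval), ]
  df$asleep <- df$activity == 0
  df$in_bout <- FALSE

  bouts <- vector("list", 0L)
  for (wid in unique(df$well_id)) {
    sel <- which(df$well_id == wid)
    r <- rle(df$asleep[sel])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_bout_intervals
    if (any(keep)) {
      for (j in which(keep)) {
        idx <- sel[starts[j]:ends[j]]
        df$in_bout[idx] <- TRUE
      }
      bouts[[length(bouts) + 1L]] <- data.frame(
        well_id = wid,
        start_interval = df$interval[sel[starts[keep]]],
        end_interval = df$interval[sel[ends[keep]]],
        n_intervals = r$lengths[keep],
        duration_s = r$lengths[keep] * dt)
    } else {
      bouts[[length(bouts) + 1L]] <- data.frame(
        well_id = character(0), start_interval = integer(0),
        end_interval = integer(0), n_intervals = integer(0),
        duration_s = numeric(0))
    }
  }
  structure(list(
    calls = df,
    bouts = do.call(rbind, bouts),
    frame_interval_s = dt,
    window = window,
    min_bout_intervals = min_bout_intervals), class = "sleep_record")
}

#' Summarize sleep per larva over an analysis window
#'
#' Totals are reported in minutes. The standard windows are the 6-hr window
#' beginning 2 hr after the molt (across-day comparisons) and the second
#' hour after the molt (circadian-time comparisons); the label is metadata
#' recorded with the summary, not computed.
#'
#' @param record a `sleep_record` from [call_sleep()].
#' @param window_label `"second-hour"`, `"six-hour"`, or `"custom"`.
#' @param circadian_label optional circadian-time tag (e.g. `"CT1"`).
#' @return data.frame with one row per well: `well_id`, `total_sleep_min`,
#'   `bout_number`, `mean_bout_length_min` (`NA` when there are no bouts),
#'   `window_label`, `circadian_label`.
#' @export
summarize_sleep <- function(record, window_label = "custom",
                            circadian_label = NA_character_) {
  stopifnot(inherits(record, "sleep_record"))
  wells <- unique(record$calls$well_id)
  rows <- lapply(wells, function(wid) {
    b <- record$bouts[record$bouts$well_id == wid, , drop = FALSE]
    total_min <- sum(b$duration_s) / 60
    nb <- nrow(b)
    data.frame(well_id = wid,
               total_sleep_min = total_min,
               bout_number = nb,
               mean_bout_length_min = if (nb > 0) total_min / nb else NA_real_,
               window_label = window_label,
               circadian_label = circadian_label)
  })
  do.call(rbind, rows)
}

#' Build a periodic stimulus schedule
#'
#' The arousal-threshold assay delivers a low-intensity 4-s light pulse
#' every 2 min for 1 hr, i.e. 30 onsets at 0, 120, ..., 3480 s.
#'
#' @param duration_s stimulus duration, seconds (default 4).
#' @param period_s seconds between onsets (default 120).
#' @param total_s total assay length, seconds (default 3600).
#' @return Object of class `stimulus_schedule` with `onsets_s`,
#'   `duration_s`, `period_s`, `total_s`.
#' @examples
#' length(make_schedule()$onsets_s)  # 30
#' @export
make_schedule <- function(duration_s = 4, period_s = 120, total_s = 3600) {
  check_positive(duration_s, "duration_s")
  check_positive(period_s, "period_s")
  check_positive(total_s, "total_s")
  if (!(duration_s < period_s && period_s <= total_s)) {
    stop("need duration_s < period_s <= total_s", call. = FALSE)
  }
  onsets <- (seq_len(ceiling(total_s / period_s)) - 1L) * period_s
  onsets <- onsets[onsets < total_s]
  structure(list(onsets_s = onsets, duration_s = duration_s,
                 period_s = period_s, total_s = total_s),
            class = "stimulus_schedule")
}

#' Score arousal responses to a stimulus schedule
#'
#' For each stimulus onset, a larva is tested if it is asleep at onset
#' (activity 0 in the interval containing the onset); a tested larva is a
#' responder if any later interval starting within `response_window_s`
#' seconds of the onset has nonzero activity. The replicate's responder
#' percentage is 100 x total responses / total tests pooled over all
#' stimuli; replicates are averaged downstream.
#'
#' @param activity an `activity_df` covering the schedule (one replicate).
#' @param schedule a [make_schedule()] stimulus schedule.
#' @param response_window_s seconds after onset in which activity counts as
#'   a response; default stimulus duration + 2 inter-frame intervals, so the
#'   window always spans at least one full frame pair after the pulse.
#' @param asleep_only score only larvae asleep at onset (the assay measures
#'   arousal from sleep); set `FALSE` to test every larva at every onset.
#' @param replicate_id identifier recorded in the result.
#' @return Object of class `arousal_result`: list with `n_larvae`,
#'   `n_tested` (larva-stimulus pairs), `n_responders`, `percent_moved`,
#'   `per_stimulus` (data.frame `onset_s`, `n_tested`, `n_responders`),
#'   `replicate_id`.
#' @export
score_arousal <- function(activity, schedule, response_window_s = NULL,
                          asleep_only = TRUE, replicate_id = NA_character_) {
  stopifnot(inherits(schedule, "stimulus_schedule"))
  dt <- attr(activity, "frame_interval_s")
  if (is.null(dt)) stop("activity lacks a frame_interval_s attribute",
                        call. = FALSE)
  response_window_s <- response_window_s %||% (schedule$duration_s + 2 * dt)
  if (response_window_s < schedule$duration_s) {
    stop("response_window_s must cover the stimulus duration", call. = FALSE)
  }
  df <- as.data.frame(activity)
  n_iv <- max(df$interval)
  if (max(schedule$onsets_s) + response_window_s > n_iv * dt) {
    stop("schedule extends past the recorded activity trace", call. = FALSE)
  }
  wells <- unique(df$well_id)
  act <- matrix(0, nrow = n_iv, ncol = length(wells),
                dimnames = list(NULL, wells))
  act[cbind(df$interval, match(df$well_id, wells))] <- df$activity

  per_stim <- lapply(schedule$onsets_s, function(t0) {
    iv0 <- floor(t0 / dt) + 1L              # interval containing the onset
    resp_iv <- which((seq_len(n_iv) - 1L) * dt > t0 &
                       (seq_len(n_iv) - 1L) * dt <= t0 + response_window_s)
    tested <- if (asleep_only) act[iv0, ] == 0 else rep(TRUE, length(wells))
    responded <- colSums(act[resp_iv, , drop = FALSE] > 0) > 0
    data.frame(onset_s = t0, n_tested = sum(tested),
               n_responders = sum(tested & responded))
  })
  per_stim <- do.call(rbind, per_stim)
  n_tested <- sum(per_stim$n_tested)
  n_resp <- sum(per_stim$n_responders)
  structure(list(
    n_larvae = length(wells),
    n_tested = n_tested,
    n_responders = n_resp,
    percent_moved = if (n_tested > 0) 100 * n_resp / n_tested else NA_real_,
    per_stimulus = per_stim,
    replicate_id = replicate_id), class = "arousal_result")
}

#' @export
print.arousal_result <- function(x, ...) {
  cat(sprintf(
    "<arousal_result> %d larvae, %d tests, %d responses (%.1f%% moved)\n",
    x$n_larvae, x$n_tested, x$n_responders, x$percent_moved))
  invisible(x)
}

#' Convert simulated ground-truth states to an activity trace
#'
#' Trace-level shortcut past image rendering: ACTIVE intervals get activity
#' 1 and QUIESCENT intervals activity 0, which is exactly what the
#' differencing pipeline recovers from a clean-mode rendered stack. Useful
#' for large simulation studies of the sleep summaries.
#'
#' @param truth list from [simulate_states()].
#' @param frame_interval_s seconds per interval.
#' @return An `activity_df`.
#' @export
truth_to_activity <- function(truth, frame_interval_s = 6) {
  rows <- lapply(truth, function(tr) {
    n <- length(tr$states)
    data.frame(well_id = tr$larva_id, interval = seq_len(n),
               time_s = (seq_len(n) - 1L) * frame_interval_s,
               activity = as.integer(tr$states == "ACTIVE"))
  })
  out <- do.call(rbind, rows)
  attr(out, "frame_interval_s") <- frame_interval_s
  attr(out, "threshold") <- NA_real_
  class(out) <- c("activity_df", "data.frame")
  out
}
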