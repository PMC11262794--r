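#' Fluorescence traces with perfusion epochs
#'
#' A `fluorescence_trace` is a long-format data.frame of per-cell raw
#' GCaMP intensities with columns `cell_id`, `time_s`, `raw_f`, `epoch`
#' (and optionally `brain_id`). Epoch labels mark the perfusion protocol:
#' `baseline`, a stimulus label (`ATP`, `CCHa1`, or `vehicle`), and
#' `washout`. Times must be strictly increasing within a cell and raw
#' fluorescence must be positive during baseline.
#'
#' @param df data.frame with the columns above.
#' @return The validated data.frame with class `fluorescence_trace`.
#' @export
fluorescence_trace <- function(df) {
  need <- c("cell_id", "time_s", "raw_f", "epoch")
  if (!is.data.frame(df) || !all(need %in% names(df))) {
    stop("trace needs columns cell_id, time_s, raw_f, epoch", call. = FALSE)
  }
  for (cid in unique(df$cell_id)) {
    d <- df[df$cell_id == cid, ]
    if (is.unsorted(d$time_s, strictly = TRUE)) {
      stop(sprintf("times not strictly increasing for cell %s", cid),
           call. = FALSE)
    }
    if (!"baseline" %in% d$epoch) {
      stop(sprintf("cell %s has no baseline epoch", cid), call. = FALSE)
    }
    if (any(d$raw_f[d$epoch == "baseline"] <= 0)) {
      stop(sprintf("cell %s has non-positive baseline fluorescence", cid),
           call. = FALSE)
    }
  }
  if (!inherits(df, "fluorescence_trace")) {
    class(df) <- c("fluorescence_trace", class(df))
  }
  df
}

#' Epoch templates for the imaging protocols
#'
#' The ATP/P2X2 protocol images every 5 s: 1 min of baseline perfusion,
#' then 2 min of ATP, then wash-in of plain buffer (the standard 3-min
#' recording covers baseline + ATP; the template also describes a 2-min
#' washout for rigs that keep acquiring). The peptide bath-application
#' protocol images every 10 s for 4 min: 1 min baseline, 2 min peptide,
#' 1 min washout. The vehicle control uses the same timings with a
#' `vehicle` stimulus label.
#'
#' @param protocol `"P2X2"`, `"CCHa1_bath"`, or `"AHL_control"`.
#' @return A list with `epochs` (data.frame `label`, `start_s`, `end_s`),
#'   `sample_interval_s`, and `recording_s` (the standard recording
#'   length).
#' @examples
#' epoch_schedule("P2X2")$sample_interval_s  # 5
#' @export
epoch_schedule <- function(protocol) {
  if (!is.character(protocol) || length(protocol) != 1L ||
      !protocol %in% c("P2X2", "CCHa1_bath", "AHL_control")) {
    stop("`protocol` must be \"P2X2\", \"CCHa1_bath\" or \"AHL_control\"",
         call. = FALSE)
  }
  switch(protocol,
    P2X2 = list(
      epochs = data.frame(
        label = c("baseline", "ATP", "washout"),
        start_s = c(0, 60, 180), end_s = c(60, 180, 300)),
      sample_interval_s = 5, recording_s = 180),
    CCHa1_bath = list(
      epochs = data.frame(
        label = c("baseline", "CCHa1", "washout"),
        start_s = c(0, 60, 180), end_s = c(60, 180, 240)),
      sample_interval_s = 10, recording_s = 240),
    AHL_control = list(
      epochs = data.frame(
        label = c("baseline", "vehicle", "washout"),
        start_s = c(0, 60, 180), end_s = c(60, 180, 240)),
      sample_interval_s = 10, recording_s = 240))
}

#' Baseline fluorescence F0
#'
#' F0 is the arithmetic mean of the raw fluorescence over the first 60 s
#' of the baseline epoch — exactly 60 s even when the recorded baseline is
#' longer.
#'
#' @param trace a single-cell [fluorescence_trace()] (one `cell_id`).
#' @param baseline_s baseline length used for the mean, seconds.
#' @return F0 (intensity units).
#' @export
baseline_f0 <- function(trace, baseline_s = 60) {
  trace <- fluorescence_trace(trace)
  if (length(unique(trace$cell_id)) != 1L) {
    stop("baseline_f0() expects a single cell; see dff_table()",
         call. = FALSE)
  }
  b <- trace[trace$epoch == "baseline", ]
  span <- max(b$time_s) - min(b$time_s) + (b$time_s[2L] - b$time_s[1L])
  if (nrow(b) < 2L || span < baseline_s) {
    stop(sprintf("baseline epoch must cover >= %g s", baseline_s),
         call. = FALSE)
  }
  t0 <- min(b$time_s)
  f0 <- mean(b$raw_f[b$time_s < t0 + baseline_s])
  if (!is.finite(f0) || f0 <= 0) stop("F0 is not positive", call. = FALSE)
  f0
}

#' Baseline-normalize a fluorescence trace
#'
#' delta F / F at sample n is (F_n - F0) / F0, with F0 from
#' [baseline_f0()] held fixed across the trace.
#'
#' @inheritParams baseline_f0
#' @return A `normalized_trace` data.frame: the input plus a `dff` column,
#'   with attribute `f0`.
#' @export
dff_trace <- function(trace, baseline_s = 60) {
  f0 <- baseline_f0(trace, baseline_s = baseline_s)
  out <- as.data.frame(trace)
  out$dff <- (out$raw_f - f0) / f0
  attr(out, "f0") <- f0
  class(out) <- c("normalized_trace", "data.frame")
  out
}

#' Maximum delta F / F during the stimulus epoch
#'
#' The per-cell response magnitude is the maximum delta F / F over samples
#' in the stimulus epoch only — fluorescence peaks during baseline or
#' washout are excluded. Equivalent to (F_max - F0) / F0 with F_max the
#' maximum raw fluorescence during stimulus application.
#'
#' @param ntrace a `normalized_trace` from [dff_trace()].
#' @param stimulus_epoch epoch label to search (e.g. `"ATP"`, `"CCHa1"`).
#' @return Maximum delta F / F (dimensionless), with the time of the
#'   maximum in attribute `t_max`.
#' @export
dff_max <- function(ntrace, stimulus_epoch = "ATP") {
  stopifnot(inherits(ntrace, "normalized_trace"))
  sel <- ntrace$epoch == stimulus_epoch
  if (!any(sel)) {
    stop(sprintf("no samples in stimulus epoch \"%s\"", stimulus_epoch),
         call. = FALSE)
  }
  i <- which(sel)[which.max(ntrace$dff[sel])]
  structure(ntrace$dff[i], t_max = ntrace$time_s[i])
}

#' Per-cell delta F / F maxima for a multi-cell recording
#'
#' Applies [dff_trace()] and [dff_max()] to every cell of a long-format
#' trace table, yielding the per-cell response table behind
#' "maximum GCaMP change" summaries.
#'
#' @param traces a [fluorescence_trace()] data.frame, possibly many cells
#'   (and a `brain_id` column, carried through if present).
#' @param stimulus_epoch epoch label to search for the maximum.
#' @param baseline_s baseline length for F0, seconds.
#' @return data.frame with one row per cell: `cell_id` (and `brain_id`),
#'   `f0`, `dff_max`, `t_max`.
#' @export
dff_table <- function(traces, stimulus_epoch = "ATP", baseline_s = 60) {
  traces <- fluorescence_trace(traces)
  rows <- lapply(unique(traces$cell_id), function(cid) {
    d <- traces[traces$cell_id == cid, ]
    nt <- dff_trace(d, baseline_s = baseline_s)
    m <- dff_max(nt, stimulus_epoch = stimulus_epoch)
    out <- data.frame(cell_id = cid, f0 = attr(nt, "f0"),
                      dff_max = as.numeric(m), t_max = attr(m, "t_max"))
    if ("brain_id" %in% names(d)) out$brain_id <- d$brain_id[1L]
    out
  })
  do.call(rbind, rows)
}
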