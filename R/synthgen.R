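#' Simulate two-state (active/quiescent) behavioral state sequences
#'
#' Each larva's behavior across inter-frame intervals is a realization of a
#' two-state Markov chain on \{ACTIVE, QUIESCENT\} with per-interval
#' transition probabilities `P(ACTIVE -> QUIESCENT) = p_sleep` and
#' `P(QUIESCENT -> ACTIVE) = p_wake`. The initial state is drawn from the
#' chain's stationary distribution, whose quiescent occupancy is
#' `p_sleep / (p_sleep + p_wake)`, so simulated occupancy is unbiased from
#' the first interval (no burn-in). When both probabilities are zero the
#' chain never moves and the initial state is a fair coin flip.
#'
#' States index inter-frame intervals: state `i` describes the change from
#' frame `i` to frame `i + 1`, matching the frame-differencing definition of
#' activity.
#'
#' @param n_larvae number of larvae (one chain each).
#' @param n_intervals number of inter-frame intervals per larva.
#' @param p_sleep probability of falling quiescent on the next interval.
#' @param p_wake probability of resuming activity on the next interval.
#' @param seed optional integer for reproducibility.
#' @return A list of ground-truth records, one per larva, each with
#'   `larva_id`, `states` (character vector of `"ACTIVE"` / `"QUIESCENT"`),
#'   `p_sleep` and `p_wake`.
#' @examples
#' truth <- simulate_states(3, 10, p_sleep = 0.2, p_wake = 0.4, seed = 1)
#' truth[[1]]$states
#' @export
simulate_states <- function(n_larvae, n_intervals, p_sleep, p_wake,
                            seed = NULL) {
  n_larvae <- check_count(n_larvae, "n_larvae")
  n_intervals <- check_count(n_intervals, "n_intervals")
  check_probability(p_sleep, "p_sleep")
  check_probability(p_wake, "p_wake")
  pi_q <- if (p_sleep + p_wake == 0) 0.5 else p_sleep / (p_sleep + p_wake)
  with_seed(seed, {
    lapply(seq_len(n_larvae), function(i) {
      s <- character(n_intervals)
      s[1L] <- if (stats::runif(1) < pi_q) "QUIESCENT" else "ACTIVE"
      if (n_intervals > 1L) {
        u <- stats::runif(n_intervals - 1L)
        for (k in 2:n_intervals) {
          s[k] <- if (s[k - 1L] == "ACTIVE") {
            if (u[k - 1L] < p_sleep) "QUIESCENT" else "ACTIVE"
          } else {
            if (u[k - 1L] < p_wake) "ACTIVE" else "QUIESCENT"
          }
        }
      }
      list(larva_id = sprintf("larva_%02d", i), states = s,
           p_sleep = p_sleep, p_wake = p_wake)
    })
  })
}

#' Rendering configuration for synthetic well-plate stacks
#'
#' Defines the well grid, blob appearance, movement and noise model used by
#' [render_stack()]. Larvae are drawn as filled ellipses (default 8 x 4 px,
#' i.e. semi-axes 4 x 2) on a uniform background; on ACTIVE intervals the
#' blob centroid moves `move_step` pixels in a uniform random direction,
#' reflecting off the well walls; on QUIESCENT intervals it holds still.
#' Per-pixel i.i.d. Gaussian noise (sd `noise_sd`) is added to every frame
#' and intensities are clipped to 0-255 and rounded to integers.
#'
#' In clean mode the contrast must satisfy
#' `blob_intensity - background_intensity >= threshold + 3 * noise_sd`,
#' and `3 * noise_sd` must stay below half the detection threshold, so that
#' (i) real movement always produces supra-threshold pixel changes and
#' (ii) noise alone essentially never does. This makes ground-truth recovery
#' by the differencing pipeline exact.
#'
#' @param n_rows,n_cols well grid dimensions.
#' @param well_px side length of each square well, pixels.
#' @param gap_px gap between wells and margin at the frame edge, pixels.
#' @param frame_interval_s seconds between frames.
#' @param blob_intensity,background_intensity gray-scale units (0-255).
#' @param noise_sd per-pixel Gaussian noise sd, gray-scale units.
#' @param move_step centroid displacement per active interval, pixels.
#' @param blob_axes semi-axes (a, b) of the larval ellipse, pixels.
#' @param clean if `TRUE`, enforce the separability constraints above against
#'   `clean_threshold`.
#' @param clean_threshold detection threshold the clean-mode guarantee is
#'   checked against (45 covers both larval-stage defaults).
#' @param seed optional integer seed used by [render_stack()].
#' @return A list of class `render_config`.
#' @export
render_config <- function(n_rows = 4L, n_cols = 5L, well_px = 40L,
                          gap_px = 4L, frame_interval_s = 6,
                          blob_intensity = 200, background_intensity = 30,
                          noise_sd = 2, move_step = 3, blob_axes = c(4, 2),
                          clean = TRUE, clean_threshold = 45, seed = NULL) {
  n_rows <- check_count(n_rows, "n_rows")
  n_cols <- check_count(n_cols, "n_cols")
  well_px <- check_count(well_px, "well_px", min = 8L)
  check_positive(noise_sd, "noise_sd", allow_zero = TRUE)
  check_positive(move_step, "move_step")
  if (clean) {
    contrast <- blob_intensity - background_intensity
    if (contrast < clean_threshold + 3 * noise_sd) {
      stop("clean mode requires blob - background contrast >= ",
           "threshold + 3 * noise_sd", call. = FALSE)
    }
    if (3 * noise_sd >= clean_threshold / 2) {
      stop("clean mode requires 3 * noise_sd < threshold / 2", call. = FALSE)
    }
  }
  if (well_px <= 2 * (max(blob_axes) + 1) + 2) {
    stop("wells too small for the blob to move inside them", call. = FALSE)
  }
  structure(list(
    n_rows = n_rows, n_cols = n_cols, well_px = well_px, gap_px = gap_px,
    frame_interval_s = frame_interval_s, blob_intensity = blob_intensity,
    background_intensity = background_intensity, noise_sd = noise_sd,
    move_step = move_step, blob_axes = blob_axes, clean = clean,
    clean_threshold = clean_threshold, seed = seed), class = "render_config")
}

# Well grid as a layout (0-based half-open rectangles), row-major well order.
layout_from_config <- function(cfg) {
  idx <- 0L
  rows <- vector("list", cfg$n_rows * cfg$n_cols)
  for (r in seq_len(cfg$n_rows)) {
    for (c in seq_len(cfg$n_cols)) {
      idx <- idx + 1L
      x0 <- cfg$gap_px + (c - 1L) * (cfg$well_px + cfg$gap_px)
      y0 <- cfg$gap_px + (r - 1L) * (cfg$well_px + cfg$gap_px)
      rows[[idx]] <- data.frame(well_id = sprintf("well_%02d", idx),
                                x0 = x0, y0 = y0,
                                x1 = x0 + cfg$well_px, y1 = y0 + cfg$well_px)
    }
  }
  well_layout(do.call(rbind, rows))
}

# Draw a filled ellipse of semi-axes ax, ay centred at (cx, cy) (pixel
# coordinates; pixel centres at integer + 0.5) into matrix `frame`.
draw_blob <- function(frame, cx, cy, ax, ay, intensity) {
  xs <- floor(cx - ax):ceiling(cx + ax)
  ys <- floor(cy - ay):ceiling(cy + ay)
  xs <- xs[xs >= 0 & xs < ncol(frame)]
  ys <- ys[ys >= 0 & ys < nrow(frame)]
  for (y in ys) {
    dx2 <- ((xs + 0.5 - cx) / ax)^2
    dy2 <- ((y + 0.5 - cy) / ay)^2
    hit <- xs[dx2 + dy2 <= 1]
    if (length(hit)) frame[y + 1L, hit + 1L] <- intensity
  }
  frame
}

reflect_into <- function(p, lo, hi) {
  # reflect a coordinate into [lo, hi]; interval assumed non-degenerate
  while (p < lo || p > hi) {
    if (p < lo) p <- 2 * lo - p else p <- 2 * hi - p
  }
  p
}

#' Render a synthetic well-plate image stack from ground-truth states
#'
#' Produces `n_intervals + 1` frames: one larva per well, drawn as a bright
#' ellipse whose centroid moves on ACTIVE intervals and holds on QUIESCENT
#' intervals (see [render_config()]). A move whose post-reflection
#' displacement falls below one pixel is redrawn so that every ACTIVE
#' interval changes at least one pixel.
#'
#' @param truth list of ground-truth records from [simulate_states()]; one
#'   well per larva, assigned in row-major well order.
#' @param cfg a [render_config()].
#' @return A list with components `stack` (an [image_stack()]), `layout`
#'   (a [well_layout()]) and `truth` (the input, with per-larva starting
#'   centroids attached).
#' @export
render_stack <- function(truth, cfg = render_config()) {
  stopifnot(inherits(cfg, "render_config"))
  n_wells <- cfg$n_rows * cfg$n_cols
  if (length(truth) > n_wells) {
    stop(sprintf("%d larvae but only %d wells in the layout",
                 length(truth), n_wells), call. = FALSE)
  }
  n_intervals <- length(truth[[1L]]$states)
  for (tr in truth) {
    if (length(tr$states) != n_intervals) {
      stop("all larvae must have the same number of intervals", call. = FALSE)
    }
  }
  layout <- layout_from_config(cfg)
  height <- cfg$gap_px + cfg$n_rows * (cfg$well_px + cfg$gap_px)
  width <- cfg$gap_px + cfg$n_cols * (cfg$well_px + cfg$gap_px)
  ax <- cfg$blob_axes[1L]
  ay <- cfg$blob_axes[2L]

  with_seed(cfg$seed, {
    n_larvae <- length(truth)
    # allowed centroid box per well: blob fully inside, 1 px slack
    box <- lapply(seq_len(n_larvae), function(i) {
      w <- layout[i, ]
      c(xlo = w$x0 + ax + 1, xhi = w$x1 - ax - 1,
        ylo = w$y0 + ay + 1, yhi = w$y1 - ay - 1)
    })
    pos <- lapply(box, function(b) {
      c(x = stats::runif(1, b["xlo"], b["xhi"]),
        y = stats::runif(1, b["ylo"], b["yhi"]))
    })
    for (i in seq_len(n_larvae)) truth[[i]]$start_xy <- unname(pos[[i]])

    frames <- vector("list", n_intervals + 1L)
    make_frame <- function(positions) {
      f <- matrix(cfg$background_intensity, nrow = height, ncol = width)
      for (i in seq_len(n_larvae)) {
        f <- draw_blob(f, positions[[i]]["x"], positions[[i]]["y"],
                       ax, ay, cfg$blob_intensity)
      }
      if (cfg$noise_sd > 0) {
        f <- f + matrix(stats::rnorm(height * width, sd = cfg$noise_sd),
                        nrow = height)
      }
      matrix(as.integer(pmin(pmax(round(f), 0), 255)), nrow = height)
    }
    frames[[1L]] <- make_frame(pos)
    for (k in seq_len(n_intervals)) {
      for (i in seq_len(n_larvae)) {
        if (truth[[i]]$states[k] == "ACTIVE") {
          b <- box[[i]]
          old <- pos[[i]]
          for (try in 1:20) {
            theta <- stats::runif(1, 0, 2 * pi)
            nx <- reflect_into(old["x"] + cfg$move_step * cos(theta),
                               b["xlo"], b["xhi"])
            ny <- reflect_into(old["y"] + cfg$move_step * sin(theta),
                               b["ylo"], b["yhi"])
            if ((nx - old["x"])^2 + (ny - old["y"])^2 >= 1) break
          }
          if ((nx - old["x"])^2 + (ny - old["y"])^2 < 1) {
            # fall back: step toward the well centre, which is always free
            cx <- (b["xlo"] + b["xhi"]) / 2
            nx <- old["x"] + cfg$move_step * sign(cx - old["x"] + 0.5)
            nx <- reflect_into(nx, b["xlo"], b["xhi"])
            ny <- old["y"]
          }
          pos[[i]] <- c(x = unname(nx), y = unname(ny))
        }
      }
      frames[[k + 1L]] <- make_frame(pos)
    }
    list(stack = image_stack(frames, frame_interval_s = cfg$frame_interval_s),
         layout = layout, truth = truth)
  })
}

#' Write ground-truth states as CSV
#'
#' Long format: one row per larva and inter-frame interval, with the
#' simulated behavioral state.
#'
#' @param truth list from [simulate_states()].
#' @param path output CSV path.
#' @export
write_ground_truth <- function(truth, path) {
  rows <- lapply(truth, function(tr) {
    data.frame(larva_id = tr$larva_id,
               interval = seq_along(tr$states),
               state = tr$states)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Simulate odor-choice counts for a conditioning group
#'
#' A group of larvae distributes over the CS+ side, the CS- side, and the
#' middle of the test plate as a single multinomial draw with probabilities
#' `(p_cs_plus, 1 - p_cs_plus - p_middle, p_middle)`.
#'
#' @param n_larvae group size (30 in the standard assay).
#' @param p_cs_plus probability of ending on the CS+ side.
#' @param p_middle probability of remaining in the middle.
#' @param side_a_label,side_b_label labels for the CS+ and CS- sides.
#' @param seed optional integer seed.
#' @return A [choice_counts()] object with `side_a` = CS+ side.
#' @export
simulate_choice_counts <- function(n_larvae, p_cs_plus, p_middle = 0,
                                   side_a_label = "CS+",
                                   side_b_label = "CS-", seed = NULL) {
  n_larvae <- check_count(n_larvae, "n_larvae")
  check_probability(p_cs_plus, "p_cs_plus")
  check_probability(p_middle, "p_middle")
  if (p_cs_plus + p_middle > 1) {
    stop("p_cs_plus + p_middle must be <= 1", call. = FALSE)
  }
  counts <- with_seed(seed, {
    stats::rmultinom(1, n_larvae,
                     c(p_cs_plus, 1 - p_cs_plus - p_middle, p_middle))[, 1L]
  })
  choice_counts(side_a = counts[1L], side_b = counts[2L],
                middle = counts[3L],
                side_a_label = side_a_label, side_b_label = side_b_label)
}

#' Parameters for simulated calcium transients
#'
#' The simulated raw fluorescence is
#' `F(t) = f0 * (1 + amplitude * kernel(t)) + noise`, where the kernel is a
#' pulse that rises linearly from `onset_s` to `onset_s + rise_s` (reaching
#' exactly 1) and then decays exponentially with time constant `decay_s`.
#' Because the peak is reached at `onset_s + rise_s`, choosing onset and
#' rise as multiples of `sample_interval_s` makes the sampled maximum hit
#' the nominal amplitude exactly in the noiseless case.
#'
#' @param f0 baseline fluorescence intensity (> 0).
#' @param amplitude peak delta F / F of the transient (>= 0).
#' @param onset_s stimulus onset, seconds; also the end of the baseline
#'   epoch.
#' @param rise_s linear rise time to peak, seconds.
#' @param decay_s exponential decay time constant, seconds.
#' @param noise_sd additive Gaussian noise sd, intensity units.
#' @param sample_interval_s seconds between samples (5 for the ATP/P2X2
#'   protocol, 10 for bath-applied peptide).
#' @param stimulus_s duration of the stimulus epoch, seconds.
#' @param stimulus_label epoch label for the stimulus (e.g. `"ATP"`).
#' @param seed optional integer seed.
#' @return A list of class `calcium_sim_params`.
#' @export
calcium_sim_params <- function(f0 = 100, amplitude = 0.5, onset_s = 60,
                               rise_s = 10, decay_s = 30, noise_sd = 1,
                               sample_interval_s = 5, stimulus_s = 120,
                               stimulus_label = "ATP", seed = NULL) {
  check_positive(f0, "f0")
  check_positive(amplitude, "amplitude", allow_zero = TRUE)
  check_positive(onset_s, "onset_s")
  check_positive(rise_s, "rise_s")
  check_positive(decay_s, "decay_s")
  check_positive(noise_sd, "noise_sd", allow_zero = TRUE)
  check_positive(sample_interval_s, "sample_interval_s")
  check_positive(stimulus_s, "stimulus_s")
  if (onset_s < sample_interval_s) {
    stop("onset_s must allow at least one baseline sample", call. = FALSE)
  }
  structure(list(f0 = f0, amplitude = amplitude, onset_s = onset_s,
                 rise_s = rise_s, decay_s = decay_s, noise_sd = noise_sd,
                 sample_interval_s = sample_interval_s,
                 stimulus_s = stimulus_s, stimulus_label = stimulus_label,
                 seed = seed), class = "calcium_sim_params")
}

#' Simulate a single-cell fluorescence trace
#'
#' @param params a [calcium_sim_params()].
#' @param n_samples number of samples; defaults to covering baseline +
#'   stimulus + one stimulus-length washout.
#' @param cell_id identifier attached to the trace.
#' @return A `fluorescence_trace` data.frame with columns `cell_id`,
#'   `time_s`, `raw_f`, `epoch` (`baseline`, the stimulus label, `washout`).
#' @export
simulate_calcium_trace <- function(params = calcium_sim_params(),
                                   n_samples = NULL, cell_id = "cell_1") {
  stopifnot(inherits(params, "calcium_sim_params"))
  dt <- params$sample_interval_s
  if (is.null(n_samples)) {
    n_samples <- floor((params$onset_s + 2 * params$stimulus_s) / dt) + 1L
  }
  n_samples <- check_count(n_samples, "n_samples", min = 2L)
  t <- (seq_len(n_samples) - 1L) * dt
  u <- t - params$onset_s
  kernel <- ifelse(u < 0, 0,
                   ifelse(u <= params$rise_s, u / params$rise_s,
                          exp(-(u - params$rise_s) / params$decay_s)))
  raw <- params$f0 * (1 + params$amplitude * kernel)
  if (params$noise_sd > 0) {
    raw <- raw + with_seed(params$seed,
                           stats::rnorm(n_samples, sd = params$noise_sd))
  }
  epoch <- ifelse(t < params$onset_s, "baseline",
                  ifelse(t < params$onset_s + params$stimulus_s,
                         params$stimulus_label, "washout"))
  fluorescence_trace(data.frame(cell_id = cell_id, time_s = t, raw_f = raw,
                                epoch = epoch))
}

#' Simulate stimulus-locked arousal activity traces
#'
#' Larvae rest (activity 0) except that, at each stimulus onset, each larva
#' responds with probability `p_respond`; a response places a positive
#' activity value in the first inter-frame interval starting after the
#' onset. This matches the arousal-threshold assay, where quiescent larvae
#' are probed with a brief low-intensity light pulse and scored for any
#' activity change.
#'
#' @param n_larvae number of larvae in the replicate.
#' @param schedule a [make_schedule()] stimulus schedule.
#' @param p_respond per-stimulus response probability.
#' @param frame_interval_s seconds between frames.
#' @param response_magnitude activity value written for a response.
#' @param seed optional integer seed.
#' @return A list: `activity` (activity data.frame as produced by
#'   [extract_activity()]) and `responded` (n_larvae x n_stimuli logical
#'   matrix of ground truth).
#' @export
simulate_arousal_traces <- function(n_larvae, schedule, p_respond,
                                    frame_interval_s = 6,
                                    response_magnitude = 25, seed = NULL) {
  n_larvae <- check_count(n_larvae, "n_larvae")
  check_probability(p_respond, "p_respond")
  stopifnot(inherits(schedule, "stimulus_schedule"))
  dt <- frame_interval_s
  n_intervals <- ceiling(schedule$total_s / dt)
  onset_iv <- floor(schedule$onsets_s / dt) + 1L  # interval containing onset
  with_seed(seed, {
    responded <- matrix(stats::runif(n_larvae * length(onset_iv)) < p_respond,
                        nrow = n_larvae)
    rows <- lapply(seq_len(n_larvae), function(i) {
      act <- integer(n_intervals)
      hit <- onset_iv[responded[i, ]] + 1L
      hit <- hit[hit <= n_intervals]
      act[hit] <- response_magnitude
      data.frame(well_id = sprintf("larva_%02d", i),
                 interval = seq_len(n_intervals),
                 time_s = (seq_len(n_intervals) - 1L) * dt,
                 activity = act)
    })
    out <- do.call(rbind, rows)
    attr(out, "frame_interval_s") <- dt
    attr(out, "threshold") <- NA_real_
    class(out) <- c("activity_df", "data.frame")
    list(activity = out, responded = responded)
  })
}
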