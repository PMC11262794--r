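#' Run a sleep experiment end to end from a configuration
#'
#' Composes the stages: read stack and layout, extract activity, call
#' sleep, summarize, and (if a stimulus schedule is configured) score
#' arousal. All outputs are CSV plus a YAML provenance record (package
#' version, configuration, config hash, seed) sufficient to reproduce the
#' run. Any stage failure aborts with the failing stage named.
#'
#' @param config list (or path to a YAML file) with entries: `stack_path`,
#'   `layout_path`, `stage` (`"L2"`/`"L3"`), optional `threshold` override,
#'   optional `window` (`c(start_s, end_s)`), optional `window_label` and
#'   `circadian_label`, optional `schedule` (list with `duration_s`,
#'   `period_s`, `total_s`), `out_dir`, optional `seed`.
#' @return Invisibly, a list with `activity`, `sleep_summary`, `arousal`
#'   (or `NULL`), and the output paths.
#' @export
run_sleep_experiment <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stage_try <- function(stage_name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage [%s] failed: %s", stage_name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  layout <- stage_try("layout", read_layout(config$layout_path))
  dt <- attr(layout, "frame_interval_s") %||% 6
  stack <- stage_try("stack",
                     read_stack(config$stack_path, frame_interval_s = dt))
  threshold <- config$threshold %||%
    default_threshold(config$stage %||% "L2")
  activity <- stage_try("activity",
                        extract_activity(stack, layout, threshold))
  window <- if (!is.null(config$window)) as.numeric(config$window) else NULL
  record <- stage_try("sleep", call_sleep(activity, window = window))
  summary <- stage_try("sleep", summarize_sleep(
    record,
    window_label = config$window_label %||% "custom",
    circadian_label = config$circadian_label %||% NA_character_))

  arousal <- NULL
  if (!is.null(config$schedule)) {
    sch <- config$schedule
    schedule <- stage_try("arousal", make_schedule(
      duration_s = sch$duration_s %||% 4,
      period_s = sch$period_s %||% 120,
      total_s = sch$total_s %||% 3600))
    arousal <- stage_try("arousal",
                         score_arousal(activity, schedule,
                                       replicate_id = config$replicate_id
                                       %||% "rep_1"))
  }

  paths <- list(activity = file.path(out_dir, "activity.csv"),
                sleep_summary = file.path(out_dir, "sleep_summary.csv"),
                provenance = file.path(out_dir, "provenance.yaml"))
  write_activity(activity, paths$activity)
  utils::write.csv(summary, paths$sleep_summary, row.names = FALSE)
  if (!is.null(arousal)) {
    paths$arousal <- file.path(out_dir, "arousal.csv")
    utils::write.csv(
      data.frame(replicate_id = arousal$replicate_id,
                 n_larvae = arousal$n_larvae, n_tested = arousal$n_tested,
                 n_responders = arousal$n_responders,
                 percent_moved = arousal$percent_moved),
      paths$arousal, row.names = FALSE)
  }
  write_provenance(paths$provenance, config)
  invisible(list(activity = activity, sleep_summary = summary,
                 arousal = arousal, paths = paths))
}

write_provenance <- function(path, config) {
  cfg_file <- tempfile(fileext = ".yaml")
  on.exit(unlink(cfg_file))
  yaml::write_yaml(config, cfg_file)
  yaml::write_yaml(list(
    package = "larvasleep",
    version = as.character(utils::packageVersion("larvasleep")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = config,
    config_md5 = unname(tools::md5sum(cfg_file)),
    seed = config$seed), path)
  invisible(path)
}

#' Self-validating synthetic demo of the whole pipeline
#'
#' Simulates a two-group circadian sleep experiment ("CT1" active phase vs
#' "CT13" rest phase, with higher quiescence occupancy at CT13), renders
#' clean-mode image stacks, runs frame differencing, sleep calling and
#' summaries, scores a simulated arousal assay, computes a performance
#' index from simulated reciprocal conditioning, and recovers delta F / F
#' maxima from simulated calcium transients. Everything is written under
#' `out_dir` as CSV plus a YAML provenance record; rerunning with the same
#' seed reproduces the CSVs byte for byte.
#'
#' @param seed integer seed for all randomness.
#' @param out_dir output directory.
#' @param n_larvae larvae per sleep group.
#' @param duration_s length of the simulated sleep recording, seconds.
#' @param occupancy_ct1,occupancy_ct13 target quiescence occupancies of the
#'   two groups' behavioral chains.
#' @param p_respond per-stimulus arousal response probability.
#' @param p_cs_plus CS+ side probability for the conditioning simulation.
#' @param n_cells simulated calcium cells.
#' @return Invisibly, a list with the group sleep table, arousal table,
#'   performance index, calcium table, and output paths.
#' @export
run_synthetic_demo <- function(seed = 1L, out_dir = "demo_out",
                               n_larvae = 30L, duration_s = 3600,
                               occupancy_ct1 = 0.25, occupancy_ct13 = 0.5,
                               p_respond = 0.8, p_cs_plus = 0.6,
                               n_cells = 20L) {
  seed <- check_count(seed, "seed", min = 0L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dt <- 6
  n_iv <- floor(duration_s / dt)
  # p_wake fixed at 0.1 per interval; p_sleep set from the target occupancy
  # pi_q = p_sleep / (p_sleep + p_wake)
  p_wake <- 0.1
  occ_to_ps <- function(occ) p_wake * occ / (1 - occ)

  grid <- grid_for(n_larvae)
  groups <- list(CT1 = occupancy_ct1, CT13 = occupancy_ct13)
  sleep_rows <- list()
  group_rows <- list()
  for (gi in seq_along(groups)) {
    label <- names(groups)[gi]
    truth <- simulate_states(n_larvae, n_iv,
                             p_sleep = occ_to_ps(groups[[gi]]),
                             p_wake = p_wake, seed = seed + 1000L * gi)
    cfg <- render_config(n_rows = grid[1L], n_cols = grid[2L],
                         seed = seed + 1000L * gi + 1L)
    rendered <- render_stack(truth, cfg)
    activity <- extract_activity(rendered$stack, rendered$layout,
                                 default_threshold("L2"))
    record <- call_sleep(activity)
    s <- summarize_sleep(record, window_label = "second-hour",
                         circadian_label = label)
    sleep_rows[[label]] <- s
    gs <- group_summary(s$total_sleep_min)
    group_rows[[label]] <- data.frame(
      circadian_label = label,
      mean_total_sleep_min = gs$mean, sem_total_sleep_min = gs$sem,
      mean_bout_number = mean(s$bout_number),
      mean_bout_length_min = mean(s$mean_bout_length_min, na.rm = TRUE),
      n = gs$n)
  }
  per_larva <- do.call(rbind, sleep_rows)
  group_table <- do.call(rbind, group_rows)

  # arousal: 4 replicates of 18 larvae under the standard schedule
  schedule <- make_schedule()
  arousal_rows <- lapply(1:4, function(r) {
    sim <- simulate_arousal_traces(18L, schedule, p_respond,
                                   seed = seed + 5000L + r)
    res <- score_arousal(sim$activity, schedule,
                         replicate_id = sprintf("rep_%d", r))
    data.frame(replicate_id = res$replicate_id, n_larvae = res$n_larvae,
               n_tested = res$n_tested, n_responders = res$n_responders,
               percent_moved = res$percent_moved)
  })
  arousal_table <- do.call(rbind, arousal_rows)

  # reciprocal conditioning: one experiment (a pair of trained groups)
  am_plus <- simulate_choice_counts(30L, p_cs_plus, side_a_label = "AM",
                                    side_b_label = "OCT",
                                    seed = seed + 7000L)
  oct_plus <- simulate_choice_counts(30L, p_cs_plus, side_a_label = "OCT",
                                     side_b_label = "AM",
                                     seed = seed + 7001L)
  pi_res <- pref_scores(am_plus, oct_plus)
  pi_table <- data.frame(pref_am_plus = pi_res$pref_am_plus,
                         pref_oct_plus = pi_res$pref_oct_plus,
                         pi = pi_res$pi)

  # calcium: ATP/P2X2-style transients, amplitude 0.5, 1% noise
  traces <- do.call(rbind, lapply(seq_len(n_cells), function(i) {
    p <- calcium_sim_params(noise_sd = 1, seed = seed + 9000L + i)
    simulate_calcium_trace(p, cell_id = sprintf("cell_%02d", i))
  }))
  calcium_table <- dff_table(fluorescence_trace(traces),
                             stimulus_epoch = "ATP")

  paths <- list(
    per_larva_sleep = file.path(out_dir, "per_larva_sleep.csv"),
    group_sleep = file.path(out_dir, "group_sleep.csv"),
    arousal = file.path(out_dir, "arousal.csv"),
    performance_index = file.path(out_dir, "performance_index.csv"),
    calcium = file.path(out_dir, "calcium_dff_max.csv"),
    provenance = file.path(out_dir, "provenance.yaml"))
  utils::write.csv(per_larva, paths$per_larva_sleep, row.names = FALSE)
  utils::write.csv(group_table, paths$group_sleep, row.names = FALSE)
  utils::write.csv(arousal_table, paths$arousal, row.names = FALSE)
  utils::write.csv(pi_table, paths$performance_index, row.names = FALSE)
  utils::write.csv(calcium_table, paths$calcium, row.names = FALSE)
  write_provenance(paths$provenance, list(
    demo = TRUE, seed = seed, n_larvae = n_larvae,
    duration_s = duration_s, occupancy_ct1 = occupancy_ct1,
    occupancy_ct13 = occupancy_ct13, p_respond = p_respond,
    p_cs_plus = p_cs_plus, n_cells = n_cells))

  invisible(list(per_larva_sleep = per_larva, group_sleep = group_table,
                 arousal = arousal_table, performance_index = pi_res,
                 calcium = calcium_table, paths = paths))
}

# smallest near-square well grid holding n larvae
grid_for <- function(n) {
  rows <- floor(sqrt(n))
  cols <- ceiling(n / rows)
  c(rows, cols)
}
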