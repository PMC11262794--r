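test_that("state simulation respects degenerate transition probabilities", {
  all_active <- simulate_states(5, 20, p_sleep = 0, p_wake = 1, seed = 1)
  for (tr in all_active) {
    expect_equal(length(tr$states), 20)
    expect_true(all(tr$states == "ACTIVE"))
  }
  sticky <- simulate_states(5, 20, p_sleep = 1, p_wake = 0, seed = 2)
  for (tr in sticky) {
    expect_true(all(tr$states[-1] == "QUIESCENT"))
  }
  expect_error(simulate_states(2, 10, p_sleep = 1.2, p_wake = 0),
               "probability")
  expect_error(simulate_states(2, 0, 0.5, 0.5), "n_intervals")
})

test_that("state simulation is reproducible and seed-isolated", {
  a <- simulate_states(3, 50, 0.2, 0.3, seed = 42)
  b <- simulate_states(3, 50, 0.2, 0.3, seed = 42)
  expect_identical(a, b)
  set.seed(777)
  before <- runif(1)
  simulate_states(3, 50, 0.2, 0.3, seed = 42)
  set.seed(777)
  expect_identical(before, runif(1))
})

test_that("stationary occupancy matches p_sleep / (p_sleep + p_wake)", {
  # pooled occupancy over many chains; the Monte-Carlo error uses the
  # Markov-chain asymptotic variance pi(1-pi)(1+rho)/(1-rho)/n, rho the
  # lag-1 autocorrelation 1 - p_sleep - p_wake
  p_sleep <- 0.1; p_wake <- 0.1
  n_iv <- 5000L; n_larvae <- 20L
  truth <- simulate_states(n_larvae, n_iv, p_sleep, p_wake, seed = 11)
  occ <- mean(vapply(truth, function(tr) mean(tr$states == "QUIESCENT"),
                     numeric(1)))
  pi_q <- p_sleep / (p_sleep + p_wake)
  rho <- 1 - p_sleep - p_wake
  se <- sqrt(pi_q * (1 - pi_q) * (1 + rho) / (1 - rho) / (n_iv * n_larvae))
  expect_lt(abs(occ - pi_q), 3 * se)
})

test_that("choice-count simulation is multinomial with the stated preference", {
  all_a <- simulate_choice_counts(30, p_cs_plus = 1, p_middle = 0, seed = 1)
  expect_equal(all_a$side_a, 30L)
  expect_equal(all_a$group_size, 30L)

  # symmetric occupancy: mean PREF over replicates ~ 0
  prefs <- vapply(1:300, function(i) {
    naive_preference(simulate_choice_counts(30, 1 / 3, 1 / 3, seed = i))
  }, numeric(1))
  expect_lt(abs(mean(prefs)), 3 * sd(prefs) / sqrt(length(prefs)))

  # p_cs_plus = 0.6, no middle: expected PREF = 0.6 - 0.4 = 0.2
  prefs2 <- vapply(1:300, function(i) {
    naive_preference(simulate_choice_counts(30, 0.6, 0, seed = 1000 + i))
  }, numeric(1))
  expect_lt(abs(mean(prefs2) - 0.2), 3 * sd(prefs2) / sqrt(length(prefs2)))

  expect_error(simulate_choice_counts(30, 0.8, 0.4), "<= 1")
})

test_that("calcium trace generator hits the nominal amplitude", {
  flat <- simulate_calcium_trace(
    calcium_sim_params(f0 = 100, amplitude = 0, noise_sd = 0))
  expect_true(all(flat$raw_f == 100))

  pulse <- simulate_calcium_trace(
    calcium_sim_params(f0 = 100, amplitude = 0.5, noise_sd = 0))
  expect_equal(max(pulse$raw_f), 150)
  expect_setequal(unique(pulse$epoch), c("baseline", "ATP", "washout"))
  # peak lies inside the stimulus epoch
  expect_equal(pulse$epoch[which.max(pulse$raw_f)], "ATP")
})

test_that("rendered stacks honor the simulated states", {
  quiet <- simulate_states(4, 8, p_sleep = 1, p_wake = 0, seed = 3)
  for (i in seq_along(quiet)) quiet[[i]]$states[] <- "QUIESCENT"
  cfg0 <- render_config(n_rows = 2, n_cols = 2, noise_sd = 0, seed = 9)
  r0 <- render_stack(quiet, cfg0)
  for (k in seq_len(7)) {
    expect_identical(r0$stack$frames[[k]], r0$stack$frames[[k + 1]])
  }

  active <- simulate_states(4, 8, p_sleep = 0, p_wake = 1, seed = 4)
  cfg1 <- render_config(n_rows = 2, n_cols = 2, seed = 10)
  r1 <- render_stack(active, cfg1)
  thr <- 45
  for (k in seq_len(8)) {
    for (w in seq_len(nrow(r1$layout))) {
      n_changed <- oracle_activity(r1$stack$frames[[k]],
                                   r1$stack$frames[[k + 1]],
                                   r1$layout[w, ], thr)
      expect_gt(n_changed, 0)
    }
  }
})

test_that("rendering is byte-deterministic under a fixed seed", {
  truth <- simulate_states(4, 10, 0.3, 0.3, seed = 5)
  cfg <- render_config(n_rows = 2, n_cols = 2, seed = 6)
  r1 <- render_stack(truth, cfg)
  r2 <- render_stack(truth, cfg)
  expect_identical(r1$stack$frames, r2$stack$frames)
})

test_that("sub-threshold rendering noise never trips the detector", {
  # difference of two independent N(0, sd) pixels has sd*sqrt(2); with the
  # clean-mode bound 3*sd < threshold/2 the observed max over 1e5 pairs
  # stays far below threshold
  sd_px <- 2; threshold <- 40
  set.seed(1234)
  d <- abs(round(rnorm(1e5, sd = sd_px)) - round(rnorm(1e5, sd = sd_px)))
  expect_lt(max(d), threshold / 2)
})

test_that("clean-mode configuration rejects inseparable settings", {
  expect_error(render_config(blob_intensity = 70, background_intensity = 30,
                             noise_sd = 2), "contrast")
  expect_error(render_config(noise_sd = 10), "3 \\* noise_sd")
  expect_silent(render_config(noise_sd = 10, clean = FALSE))
  truth <- simulate_states(5, 4, 0.5, 0.5, seed = 1)
  expect_error(render_stack(truth, render_config(n_rows = 2, n_cols = 2)),
               "wells")
})
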