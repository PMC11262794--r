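test_that("sleep calls and bouts follow the zero-activity definition", {
  act <- activity_from_vector(c(0, 0, 0, 5, 0))
  rec <- call_sleep(act)
  expect_equal(rec$bouts$duration_s, c(18, 6))
  expect_equal(rec$bouts$start_interval, c(1, 5))
  expect_equal(sum(rec$bouts$duration_s), 24)

  hour <- activity_from_vector(rep(0, 600))
  rec2 <- call_sleep(hour)
  expect_equal(nrow(rec2$bouts), 1)
  expect_equal(rec2$bouts$duration_s, 3600)
  s <- summarize_sleep(rec2)
  expect_equal(s$total_sleep_min, 60)
})

test_that("bout decomposition equals the run-length oracle", {
  set.seed(303)
  for (i in 1:200) {
    v <- rbinom(sample(5:80, 1), 1, runif(1)) * sample(0:3, 1)
    min_len <- sample(1:3, 1)
    rec <- call_sleep(activity_from_vector(v), min_bout_intervals = min_len)
    ora <- oracle_bouts(v == 0, min_len)
    expect_equal(rec$bouts$start_interval, ora$start)
    expect_equal(rec$bouts$end_interval, ora$end)
    expect_equal(rec$bouts$n_intervals, ora$len)
  }
})

test_that("sleep summaries report minutes, counts and missing means", {
  rec <- call_sleep(activity_from_vector(c(0, 0, 0, 5, 0)))
  s <- summarize_sleep(rec, window_label = "custom")
  expect_equal(s$total_sleep_min, 0.4)
  expect_equal(s$bout_number, 2)
  expect_equal(s$mean_bout_length_min, 0.2)

  awake <- call_sleep(activity_from_vector(c(3, 1, 4, 1, 5)))
  s0 <- summarize_sleep(awake)
  expect_equal(s0$total_sleep_min, 0)
  expect_equal(s0$bout_number, 0)
  expect_true(is.na(s0$mean_bout_length_min))
})

test_that("sleep plus wake time conserves the window length", {
  set.seed(404)
  dt <- 6
  for (i in 1:50) {
    n <- sample(20:200, 1)
    v <- rbinom(n, 1, runif(1)) * 7
    rec <- call_sleep(activity_from_vector(v, dt = dt))
    sleep_s <- sum(rec$bouts$duration_s)
    wake_s <- sum(!rec$calls$asleep) * dt
    expect_equal(sleep_s + wake_s, n * dt)
    expect_equal(sleep_s, sum(rec$calls$asleep) * dt)
  }
})

test_that("windowing restricts the analyzed intervals", {
  v <- c(0, 0, 5, 0, 0, 0, 5, 5)
  rec <- call_sleep(activity_from_vector(v), window = c(12, 36))
  # intervals starting at 12, 18, 24, 30 -> activities 5, 0, 0, 0
  expect_equal(nrow(rec$calls), 4)
  expect_equal(rec$bouts$duration_s, 18)
  expect_error(call_sleep(activity_from_vector(v), window = c(100, 200)),
               "no inter-frame")
})

test_that("stimulus schedules enumerate onsets correctly", {
  expect_equal(length(make_schedule(4, 120, 3600)$onsets_s), 30)
  expect_equal(make_schedule(4, 120, 3600)$onsets_s[30], 3480)
  expect_equal(length(make_schedule(4, 3600, 3600)$onsets_s), 1)
  expect_error(make_schedule(5, 4, 3600), "duration_s < period_s")
})

test_that("arousal scoring counts sleeping responders in the window", {
  sch <- make_schedule(4, 120, 360)  # 3 onsets: 0, 120, 240
  # larva A responds to every stimulus, larva B to none
  n_iv <- 62
  a <- integer(n_iv); a[c(2, 22, 42)] <- 9
  b <- integer(n_iv)
  act <- rbind(activity_from_vector(a, "A"), activity_from_vector(b, "B"))
  attr(act, "frame_interval_s") <- 6
  class(act) <- c("activity_df", "data.frame")
  res <- score_arousal(act, sch)
  expect_equal(res$n_tested, 6)
  expect_equal(res$n_responders, 3)
  expect_equal(res$percent_moved, 50)

  # a larva active at onset is not tested when asleep_only = TRUE
  c_ <- integer(n_iv); c_[21] <- 9  # active in the interval containing 120 s
  act2 <- activity_from_vector(c_, "C")
  res2 <- score_arousal(act2, sch)
  expect_equal(res2$n_tested, 2)
  expect_equal(res2$n_responders, 0)
  res2b <- score_arousal(act2, sch, asleep_only = FALSE)
  expect_equal(res2b$n_tested, 3)

  # activity after the response window does not count
  d <- integer(n_iv); d[10] <- 9  # 54 s after the onset at 0
  res3 <- score_arousal(activity_from_vector(d, "D"), sch)
  expect_equal(res3$n_responders, 0)

  expect_error(score_arousal(activity_from_vector(integer(10), "E"), sch),
               "extends past")
})

test_that("simulated arousal traces recover the response probability", {
  sch <- make_schedule()
  sim <- simulate_arousal_traces(18, sch, p_respond = 0.8, seed = 55)
  res <- score_arousal(sim$activity, sch)
  expect_equal(res$n_tested, 18 * 30)
  expect_equal(res$n_responders, sum(sim$responded))
  p_hat <- res$percent_moved / 100
  expect_lt(abs(p_hat - 0.8), 3 * sqrt(0.8 * 0.2 / (18 * 30)))
})

test_that("group sleep reflects the simulated occupancy", {
  # occupancy 0.5 over 30 min at 6 s framing, 30 larvae
  truth <- simulate_states(30, 300, p_sleep = 0.1, p_wake = 0.1, seed = 66)
  act <- truth_to_activity(truth)
  s <- summarize_sleep(call_sleep(act))
  gs <- group_summary(s$total_sleep_min)
  expect_lt(abs(gs$mean - 15), 3 * gs$sem)
})
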