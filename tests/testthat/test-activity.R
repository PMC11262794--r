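test_that("stage defaults give the documented thresholds", {
  expect_equal(default_threshold("L2"), 40)
  expect_equal(default_threshold("L3"), 45)
  expect_error(default_threshold("L1"), "L2")
})

test_that("threshold comparison is >= on the absolute change", {
  base <- matrix(100, 8, 8)
  well <- list(x0 = 0, y0 = 0, x1 = 8, y1 = 8)
  for (thr in c(40, 45)) {
    below <- base; below[3, 3] <- 100 + thr - 1
    at <- base; at[3, 3] <- 100 + thr
    expect_equal(frame_pair_activity(base, below, well, thr), 0)
    expect_equal(frame_pair_activity(base, at, well, thr), 1)
    # negative-going change of the same magnitude also counts
    down <- base; down[3, 3] <- 100 - thr
    expect_equal(frame_pair_activity(base, down, well, thr), 1)
  }
})

test_that("activity equals the brute-force per-pixel oracle", {
  set.seed(101)
  for (i in 1:200) {
    fa <- random_frame(); fb <- random_frame()
    x0 <- sample(0:8, 1); y0 <- sample(0:8, 1)
    well <- list(x0 = x0, y0 = y0,
                 x1 = x0 + sample(1:(16 - x0), 1),
                 y1 = y0 + sample(1:(16 - y0), 1))
    thr <- sample(c(10, 40, 45, 200), 1)
    expect_identical(frame_pair_activity(fa, fb, well, thr),
                     oracle_activity(fa, fb, well, thr))
  }
})

test_that("activity is symmetric, monotone in the threshold, and local", {
  set.seed(202)
  fa <- random_frame(); fb <- random_frame()
  well <- list(x0 = 2, y0 = 3, x1 = 10, y1 = 12)
  expect_equal(frame_pair_activity(fa, fb, well, 40),
               frame_pair_activity(fb, fa, well, 40))
  acts <- vapply(c(10, 20, 40, 45, 100, 256),
                 function(t) frame_pair_activity(fa, fb, well, t),
                 numeric(1))
  expect_true(all(diff(acts) <= 0))
  # perturbing pixels outside the well leaves activity unchanged
  fb2 <- fb
  fb2[1, ] <- 255 - fb2[1, ]  # row y = 0, outside y0 = 3
  expect_equal(frame_pair_activity(fa, fb2, well, 40),
               frame_pair_activity(fa, fb, well, 40))
  expect_error(frame_pair_activity(fa, fb, list(x0 = 0, y0 = 0, x1 = 17,
                                                y1 = 16), 40),
               "outside")
})

test_that("changes straddling two wells are split without loss", {
  fa <- matrix(0, 10, 20)
  fb <- fa
  fb[5, 8:13] <- 100  # columns x = 7..12 cross the x = 10 boundary
  wells <- well_layout(data.frame(
    well_id = c("left", "right"),
    x0 = c(0, 10), y0 = c(0, 0), x1 = c(10, 20), y1 = c(10, 10)))
  left <- frame_pair_activity(fa, fb, wells[1, ], 40)
  right <- frame_pair_activity(fa, fb, wells[2, ], 40)
  expect_equal(left, 3)   # x = 7, 8, 9
  expect_equal(right, 3)  # x = 10, 11, 12
  full <- list(x0 = 0, y0 = 0, x1 = 20, y1 = 10)
  expect_equal(left + right, frame_pair_activity(fa, fb, full, 40))
})

test_that("extract_activity produces one trace per well in interval order", {
  frames <- list(matrix(50, 30, 30), matrix(50, 30, 30))
  stack <- image_stack(frames, frame_interval_s = 6)
  wells <- well_layout(data.frame(
    well_id = sprintf("w%02d", 1:9),
    x0 = rep(c(0, 10, 20), 3), y0 = rep(c(0, 10, 20), each = 3),
    x1 = rep(c(10, 20, 30), 3), y1 = rep(c(10, 20, 30), each = 3)))
  act <- extract_activity(stack, wells, 40)
  expect_equal(nrow(act), 9)
  expect_true(all(act$activity == 0))
  expect_equal(attr(act, "threshold"), 40)
  expect_equal(unique(act$time_s), 0)
})

test_that("the differencing pipeline recovers clean-mode ground truth", {
  truth <- simulate_states(6, 40, p_sleep = 0.3, p_wake = 0.3, seed = 21)
  r <- render_stack(truth, render_config(n_rows = 2, n_cols = 3, seed = 22))
  act <- extract_activity(r$stack, r$layout, default_threshold("L2"))
  for (i in seq_along(truth)) {
    a <- act$activity[act$well_id == r$layout$well_id[i]]
    expect_identical(a > 0, truth[[i]]$states == "ACTIVE")
  }
})

test_that("TIFF stacks and layout files round-trip", {
  truth <- simulate_states(4, 6, 0.5, 0.5, seed = 31)
  r <- render_stack(truth, render_config(n_rows = 2, n_cols = 2, seed = 32))
  tif <- tempfile(fileext = ".tif")
  write_stack(r$stack, tif)
  back <- read_stack(tif, frame_interval_s = 6)
  expect_equal(length(back$frames), length(r$stack$frames))
  for (k in seq_along(back$frames)) {
    expect_equal(back$frames[[k]], r$stack$frames[[k]],
                 ignore_attr = TRUE)
  }
  for (ext in c(".json", ".yaml")) {
    f <- tempfile(fileext = ext)
    write_layout(r$layout, f, frame_interval_s = 6, seed = 32)
    lay <- read_layout(f)
    expect_equal(as.data.frame(lay), as.data.frame(r$layout),
                 ignore_attr = TRUE)
    expect_equal(attr(lay, "frame_interval_s"), 6)
  }
})
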