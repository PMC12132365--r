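test_that("cdk2_low_duration counts threshold crossings exactly", {
  # 96 h at 12-min frames = 480 frames
  below <- trace_set(matrix(0.5, 1, 480), frame_interval_min = 12)
  expect_equal(as.numeric(cdk2_low_duration(below, 0.8)), 96)
  above <- trace_set(matrix(1.2, 1, 480), frame_interval_min = 12)
  expect_equal(as.numeric(cdk2_low_duration(above, 0.8)), 0)
  alt <- trace_set(matrix(rep(c(0.5, 1.2), 240), 1, 480, byrow = TRUE),
                   frame_interval_min = 12)
  expect_equal(as.numeric(cdk2_low_duration(alt, 0.8)), 48)
})

test_that("masked frames drop out of duration and movie length", {
  v <- matrix(0.5, 2, 100)
  mask <- matrix(FALSE, 2, 100)
  mask[2, 1:50] <- TRUE
  ts <- trace_set(v, frame_interval_min = 12, mask = mask)
  dur <- cdk2_low_duration(ts, 0.8)
  expect_equal(as.numeric(dur), c(20, 10))
  expect_equal(unname(attr(dur, "movie_hours")), c(20, 10))
})

test_that("classify_cycle applies cutoffs with monotone behavior", {
  dur <- c(a = 0, b = 5, c = 30, d = 91.2, e = 96)
  out <- classify_cycle(dur, movie_hours = 96, fast_max = 12,
                        senescent_min = 91.2)
  expect_identical(out$category,
                   c("fast_cycling", "fast_cycling", "slow_cycling",
                     "predicted_senescent", "predicted_senescent"))
  # monotonicity: increasing duration never moves toward fast
  lv <- c(fast_cycling = 1, slow_cycling = 2, predicted_senescent = 3)
  grid <- seq(0, 96, by = 0.5)
  cls <- classify_cycle(setNames(grid, seq_along(grid)), 96)$category
  expect_true(all(diff(lv[cls]) >= 0))
  expect_error(classify_cycle(dur, 96, fast_max = 50,
                              senescent_min = 40), "fast_max")
})

test_that("entry_fraction_curve is bounded and mixture-monotone", {
  sen <- simulate_traces(100, c(0, 0, 1), noise_sd = 0, seed = 2)
  expect_true(all(entry_fraction_curve(sen$traces, 0.8) == 0))
  allhigh <- trace_set(matrix(1.1, 5, 10), frame_interval_min = 12)
  expect_true(all(entry_fraction_curve(allhigh, 0.8) == 1))
  # larger senescent fraction => pointwise lower entry curve
  lo <- simulate_traces(400, c(0.7, 0, 0.3), noise_sd = 0, seed = 5)
  hi <- simulate_traces(400, c(0.3, 0, 0.7), noise_sd = 0, seed = 5)
  c_lo <- entry_fraction_curve(lo$traces, 0.8)
  c_hi <- entry_fraction_curve(hi$traces, 0.8)
  expect_true(mean(c_lo - c_hi) > 0.2)
  expect_true(all(c_lo >= c_hi - 0.12))
})

test_that("duration and entry fraction are mutually consistent", {
  set.seed(15)
  v <- matrix(runif(20 * 50, 0.4, 1.2), 20, 50)
  ts <- trace_set(v, frame_interval_min = 12)
  low_frames <- rowSums(v < 0.8)
  high_frames_total <- sum(v > 0.8)
  dur <- cdk2_low_duration(ts, 0.8)
  expect_equal(as.numeric(dur), unname(low_frames) * 12 / 60)
  # a frame counted as entered is never counted as low
  expect_equal(sum(entry_fraction_curve(ts, 0.8) * 20) +
                 sum(low_frames), 20 * 50)
  expect_equal(sum(entry_fraction_curve(ts, 0.8) * 20),
               high_frames_total)
})

test_that("reporter_slope recovers exact slopes and validates input", {
  # baseline 100, post-induction +10 per frame at 12-min frames:
  # normalized slope 0.1/frame = 0.5/hour
  v <- matrix(100, 1, 30)
  v[1, 11:30] <- 100 + 10 * (1:20)
  ts <- trace_set(v, frame_interval_min = 12, induction_frame = 10)
  sl <- reporter_slope(ts, fit_window = 11:30)
  expect_equal(sl$slope_per_frame, 0.1, tolerance = 1e-10)
  expect_equal(sl$slope_per_hour, 0.5, tolerance = 1e-10)
  flat <- trace_set(matrix(50, 1, 30), frame_interval_min = 12,
                    induction_frame = 10)
  expect_equal(reporter_slope(flat, 11:30)$slope_per_frame, 0,
               tolerance = 1e-12)
  expect_error(reporter_slope(ts, fit_window = 5:20), "after induction")
  expect_error(reporter_slope(ts, fit_window = 11:12), "3 frames")
  neg <- trace_set(matrix(-1, 1, 30), frame_interval_min = 12,
                   induction_frame = 10)
  expect_error(reporter_slope(neg, 11:30), "mean <= 0")
})

test_that("reporter slope classes separate by > 5 pooled SDs", {
  sim <- simulate_reporter_traces(
    200, c(slow = 0.10, senescent = 0.02), induction_frame = 20,
    n_frames = 120, noise_sd = 0.01, seed = 13)
  sl <- reporter_slope(sim$traces, fit_window = 25:80)
  by_class <- split(sl$slope_per_frame, sim$truth$class)
  m <- vapply(by_class, mean, numeric(1))
  s <- vapply(by_class, sd, numeric(1))
  pooled <- sqrt(mean(s^2))
  expect_gt(abs(m["slow"] - m["senescent"]) / pooled, 5)
})

test_that("dna_saddle_split finds the valley of a clear 2N/4N mixture", {
  set.seed(19)
  dna <- c(rnorm(300, 2, 0.1), rnorm(300, 4, 0.1))
  out <- dna_saddle_split(dna)
  expect_false(out$flag)
  expect_gt(out$threshold, 2.5)
  expect_lt(out$threshold, 3.5)
  truth <- rep(c("2N", "4N"), each = 300)
  expect_gte(mean(out$labels == truth), 0.99)
  expect_equal(sum(table(out$labels)), 600)
})

test_that("unimodal DNA content is flagged without a split", {
  set.seed(23)
  out <- dna_saddle_split(rnorm(200, 2, 0.1))
  expect_true(out$flag)
  expect_true(is.na(out$threshold))
  expect_true(all(is.na(out$labels)))
  expect_error(dna_saddle_split(rnorm(10, 2, 0.1)), "at least 50")
  expect_error(dna_saddle_split(c(rnorm(100, 2, 0.1), -1)), "positive")
})

test_that("trace classification recovers generator labels", {
  sim <- simulate_traces(300, c(1, 1, 1) / 3, noise_sd = 0, seed = 29)
  dur <- cdk2_low_duration(sim$traces, 0.8)
  movie <- 480 * 12 / 60
  cls <- classify_cycle(dur, movie)
  map <- c(fast = "fast_cycling", slow = "slow_cycling",
           senescent = "predicted_senescent")
  expect_gte(mean(cls$category == map[sim$truth$behavior]), 0.95)
})

test_that("long/wide trace CSV round-trips through read_traces", {
  v <- matrix(round(runif(6), 3), 2, 3)
  rownames(v) <- c("a", "b")
  long <- data.frame(cell_id = rep(c("a", "b"), each = 3),
                     frame = rep(1:3, 2),
                     value = c(v[1, ], v[2, ]))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(long, path, row.names = FALSE)
  ts <- read_traces(path, frame_interval_min = 12, format = "long")
  expect_equal(unname(ts$values), unname(v))
  wide <- data.frame(cell_id = c("a", "b"), f1 = v[, 1], f2 = v[, 2],
                     f3 = v[, 3])
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(wide, path2, row.names = FALSE)
  ts2 <- read_traces(path2, frame_interval_min = 12, format = "wide")
  expect_equal(unname(ts2$values), unname(v))
})
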