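test_that("interval table computes durations and disambiguates sessions", {
  ann <- annotation_recording("A", data.frame(start = 7.070, end = 7.730,
                                              compDepth = 59.520001))
  tab <- build_interval_table(
    mlt_session("s1", annotation_recordings = list(ann)))
  expect_equal(tab$duration, 0.660, tolerance = 1e-9)
  expect_identical(nrow(tab), 1L)

  # empty annotation recording -> empty table
  empty <- build_interval_table(mlt_session("s0"))
  expect_identical(nrow(empty), 0L)

  # identical relative times in two sessions stay distinct via the datetime
  s1 <- mlt_session("s1", annotation_recordings = list(ann),
                    recording_datetime = as.POSIXct("2019-01-01", tz = "UTC"))
  s2 <- mlt_session("s2", annotation_recordings = list(ann),
                    recording_datetime = as.POSIXct("2019-01-02", tz = "UTC"))
  both <- build_interval_table(list(s1, s2))
  expect_identical(nrow(both), 2L)
  expect_identical(length(unique(both$abs_start)), 2L)
  expect_identical(length(unique(both$start)), 1L)

  bad <- annotation_recording("A", data.frame(start = 1, end = 2))
  bad$intervals$end <- 0.5  # bypass constructor to hit the table validation
  expect_error(build_interval_table(
    mlt_session("sx", annotation_recordings = list(bad))), "end <= start")
})

test_that("attribute table sanitises, prunes, excludes and dedups", {
  fr <- data.frame(timestamp = c(0, 0.1, 0.1, 0.2),
                   check.names = FALSE)
  fr[["Kinect.Hand_LeftY"]] <- c(1, 2, 99, 3)   # underscore + dot removed
  fr[["Kinect.HeadZ"]] <- c(2, 2, 2, 2)          # excluded joint
  fr[["Myo.Dead"]] <- c(0, 0, 0, 0)              # zero running total
  rec <- sensor_recording("K", fr)
  tab <- build_attribute_table(rec)
  expect_identical(names(tab), c("timestamp", "KinectHandLeftY"))
  expect_identical(nrow(tab), 3L)                 # duplicate 0.1 dropped
  expect_equal(tab$KinectHandLeftY, c(1, 2, 3))   # keep-first on ties
  expect_identical(attr(tab, "dropped_excluded"), "KinectHeadZ")
  expect_identical(attr(tab, "dropped_zero"), "MyoDead")

  # nothing survives -> hard error
  only_dead <- sensor_recording("K", data.frame(timestamp = 0:1,
                                                Z = c(0, 0)))
  expect_error(build_attribute_table(only_dead), "no attributes survive")
  expect_error(build_attribute_table(list()), "at least one")
})

test_that("streams at different rates merge sparsely, densify on request", {
  s <- make_toy_session(1)
  tab <- build_attribute_table(s)
  expect_true("KinectHandLeftY" %in% names(tab))
  expect_false("KinectHeadZ" %in% names(tab))     # excluded by default
  expect_true(all(c("MyoEMGPod0", "MyoAccY") %in% names(tab)))
  expect_true(!is.unsorted(tab$timestamp))
  # rows from one device are NA on the other's columns
  expect_true(anyNA(tab$KinectHandLeftY))
  dense <- as_dense_attribute_table(tab)
  expect_false(anyNA(dense))
})

test_that("masking is half-open and assigns each update at most once", {
  tab <- structure(data.frame(timestamp = c(7.0, 7.5, 7.730, 7.8),
                              a = c(1, 2, 3, 4)),
                   class = c("attribute_table", "data.frame"))
  iv <- data.frame(start = c(7.070, 7.730), end = c(7.730, 8.5))
  masks <- mask_by_intervals(tab, iv)
  expect_identical(masks[[1]]$times, 7.5)           # 7.0 before, 7.730 == end
  expect_identical(masks[[2]]$times, c(7.730, 7.8)) # boundary joins next one
  # every update in at most one mask
  all_t <- c(masks[[1]]$times, masks[[2]]$times)
  expect_identical(anyDuplicated(all_t), 0L)

  expect_error(mask_by_intervals(tab, data.frame(start = c(0, 0.5),
                                                 end = c(1, 1.5))),
               "overlap")
  expect_warning(mask_by_intervals(tab, data.frame(start = 100, end = 101)),
                 "no sensor updates")
})

test_that("simulated sessions give every interval at least one update", {
  sim <- simulate_session(simulation_params(duration_s = 20, seed = 6))
  tab <- build_attribute_table(sim$session)
  gt <- sim$ground_truth
  expect_true(all(gt$end - gt$start >= 0.44))  # 30 Hz * 0.44 s > 13 samples
  masks <- mask_by_intervals(tab, gt)
  expect_true(all(vapply(masks, function(m) length(m$times) > 0, TRUE)))
})

test_that("resampling matches trivial closed forms", {
  m <- list(start = 0, end = 1, times = seq(0, 0.99, by = 0.01),
            values = matrix(5, 100, 1, dimnames = list(NULL, "a")))
  out <- resample_to_bins(m, S = 8)
  expect_equal(unname(out[, 1]), rep(5, 8))

  m$values <- matrix(rnorm(100), 100, 1, dimnames = list(NULL, "a"))
  expect_equal(unname(resample_to_bins(m, S = 1)[1, 1]), mean(m$values))

  empty <- list(start = 0, end = 1, times = numeric(0),
                values = matrix(numeric(0), 0, 1))
  expect_error(resample_to_bins(empty), "zero updates")
})

test_that("resampler equals the brute-force oracle (property, 1000+ cases)", {
  set.seed(77)
  for (case in seq_len(1000)) {
    n <- sample(1:25, 1)
    start <- runif(1, 0, 10)
    end <- start + runif(1, 0.2, 1)
    times <- sort(runif(n, start, end - 1e-9))
    vals <- rnorm(n) + seq_len(n) * runif(1, -1, 1)  # irregular ramps
    m <- list(start = start, end = end, times = times,
              values = matrix(vals, n, 1, dimnames = list(NULL, "a")))
    got <- resample_to_bins(m, S = 8)[, 1]
    counts <- oracle_bin_counts(times, start, end, 8)
    want <- oracle_resample(times, vals, start, end, 8)
    # exact equality on non-empty bins; interpolation agreement elsewhere
    expect_equal(unname(got[counts > 0]), want[counts > 0], tolerance = 1e-12)
    expect_equal(unname(got), want, tolerance = 1e-9)
  }
})

test_that("bin means preserve the per-bin-mean average exactly", {
  set.seed(78)
  # >= 1 update per bin by construction
  times <- sort(c(seq(0.05, 0.95, length.out = 8) + runif(8, -0.04, 0.04),
                  runif(20, 0, 0.999)))
  vals <- rnorm(length(times))
  m <- list(start = 0, end = 1, times = times,
            values = matrix(vals, length(vals), 1,
                            dimnames = list(NULL, "a")))
  got <- resample_to_bins(m, S = 8)[, 1]
  want <- oracle_resample(times, vals, 0, 1, 8)
  expect_identical(sum(oracle_bin_counts(times, 0, 1, 8) == 0), 0L)
  expect_equal(mean(got), mean(want), tolerance = 1e-12)
})

test_that("empty bins are linearly interpolated, edges extended", {
  # updates only in bins 2 and 6 (bin width 0.125)
  m <- list(start = 0, end = 1, times = c(0.19, 0.69),
            values = matrix(c(2, 10), 2, 1, dimnames = list(NULL, "a")))
  out <- resample_to_bins(m, S = 8)[, 1]
  expect_equal(unname(out), c(2, 2, 4, 6, 8, 10, 10, 10))
})

test_that("tensor assembly stacks, scales and validates", {
  mk <- function(x) matrix(x, 8, 2, dimnames = list(NULL, c("a", "b")))
  tens <- assemble_tensor(list(mk(1:16), mk(17:32), mk(33:48)))
  expect_identical(dim(tens$values), c(3L, 8L, 2L))
  expect_true(all(tens$values >= 0 & tens$values <= 1))
  expect_equal(max(tens$values[, , "a"]), 1)
  expect_equal(min(tens$values[, , "a"]), 0)
  expect_identical(tens$scaling$attribute, c("a", "b"))

  # constant attribute scales to 0 everywhere
  cm <- matrix(c(rep(7, 8), 1:8), 8, 2, dimnames = list(NULL, c("c", "d")))
  t2 <- assemble_tensor(list(cm, cm))
  expect_true(all(t2$values[, , "c"] == 0))

  bad <- matrix(1, 8, 3, dimnames = list(NULL, c("a", "b", "x")))
  expect_error(assemble_tensor(list(mk(1:16), bad)), "inconsistent")
})

test_that("end-to-end tensor rows equal the ground-truth compression count", {
  sim <- simulate_session(simulation_params(duration_s = 20, seed = 12))
  prep <- sessions_to_tensor(sim$session)
  expect_identical(dim(prep$tensor$values)[1], nrow(sim$ground_truth))
  expect_identical(nrow(prep$intervals), nrow(sim$ground_truth))
  expect_true(all(prep$tensor$values >= 0 & prep$tensor$values <= 1))
})
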