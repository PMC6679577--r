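test_that("compression count and determinism follow the parameters", {
  p <- simulation_params(rate_cpm = 110, duration_s = 120,
                         rate_jitter_cpm = 0, depth_jitter_mm = 0,
                         release_jitter_mm = 0, sensor_noise_sd = 0, seed = 1)
  sim <- simulate_session(p)
  expect_identical(nrow(sim$ground_truth), 220L)  # 110/min x 2 min

  pj <- simulation_params(duration_s = 20, seed = 7)
  a <- simulate_session(pj)
  b <- simulate_session(pj)
  expect_identical(a$ground_truth, b$ground_truth)
  expect_identical(a$session$sensor_recordings$Kinect$frames,
                   b$session$sensor_recordings$Kinect$frames)
  c <- simulate_session(simulation_params(duration_s = 20, seed = 8))
  expect_false(isTRUE(all.equal(a$ground_truth$compDepth,
                                c$ground_truth$compDepth)))

  expect_error(simulate_session(simulation_params(duration_s = 0.2)),
               "too short")
})

test_that("ground-truth intervals are ordered, non-overlapping and in range", {
  sim <- simulate_session(simulation_params(duration_s = 30, seed = 3))
  gt <- sim$ground_truth
  expect_true(all(diff(gt$start) > 0))
  expect_true(all(gt$end > gt$start))
  expect_true(all(gt$start[-1] >= gt$end[-nrow(gt)] - 1e-9))
  expect_true(all(gt$compRelease >= 0))
  expect_true(all(gt$compDepth > gt$compRelease))
})

test_that("the session carries the advertised attribute sets", {
  sim <- simulate_session(simulation_params(duration_s = 5, seed = 2))
  kin <- sim$session$sensor_recordings$Kinect$frames
  myo <- sim$session$sensor_recordings$Myo$frames
  expect_identical(ncol(kin) - 1L, 45L)  # 15 joints x X/Y/Z
  expect_identical(ncol(myo) - 1L, 18L)  # 8 EMG + acc + gyro + quaternion
  expect_true(all(c("Kinect.HandLeftY", "Kinect.AnkleRightZ",
                    "Kinect.HeadX") %in% names(kin)))
  expect_true(all(c("Myo.EMGPod0", "Myo.EMGPod7", "Myo.AccY",
                    "Myo.GyrX", "Myo.OriW") %in% names(myo)))
})

test_that("manikin emulator matches closed forms on constructed waveforms", {
  # pure 2 Hz raised cosine, amplitude 55, full release
  t <- seq(0, 5, by = 0.002)
  d <- 55 * (1 - cos(2 * pi * 2 * t)) / 2
  em <- manikin_emulate(d, t, seq(0, 5, by = 0.5))
  expect_equal(em$compMeanRate, rep(120, 10))
  expect_equal(em$compDepth, rep(55, 10), tolerance = 0.01)
  expect_equal(em$compRelease, rep(0, 10), tolerance = 0.01)

  # waveform clamped at a 6 mm floor -> release ~ 6
  d2 <- pmax(6, d)
  em2 <- manikin_emulate(d2, t, seq(0, 5, by = 0.5))
  expect_equal(em2$compRelease, rep(6, 10), tolerance = 0.05)

  # fewer than one cycle -> empty output
  expect_identical(nrow(manikin_emulate(d[1:3], t[1:3], c(0))), 0L)
})

test_that("noise-free simulation round-trips through the emulator", {
  p <- simulation_params(rate_cpm = 110, depth_mm = 55, release_mm = 2,
                         duration_s = 30, rate_jitter_cpm = 0,
                         depth_jitter_mm = 0, release_jitter_mm = 0,
                         sensor_noise_sd = 0, seed = 5)
  sim <- simulate_session(p)
  gt <- sim$ground_truth
  tr <- extract_displacement(sim$session)
  em <- manikin_emulate(tr$displacement_mm, tr$time,
                        c(gt$start, gt$end[nrow(gt)]))
  expect_identical(nrow(em), nrow(gt))
  expect_lt(max(abs(em$compDepth - 55)), 0.5)
  expect_lt(max(abs(em$compRelease - 2)), 0.5)
  expect_lt(max(abs(em$compMeanRate - 110)), 1)
  lab <- label_compressions(em)
  expect_true(all(lab$classRate == 1L))
  expect_true(all(lab$classDepth == 1L))
  expect_true(all(lab$classRelease == 1L))
})

test_that("jittered per-cycle rates are recovered against ground truth", {
  sim <- simulate_session(simulation_params(duration_s = 30, seed = 11))
  gt <- sim$ground_truth
  tr <- extract_displacement(sim$session)
  em <- manikin_emulate(tr$displacement_mm, tr$time,
                        c(gt$start, gt$end[nrow(gt)]))
  expect_lt(max(abs(em$compMeanRate - gt$compMeanRate)), 2)
})

test_that("mistake injection separates the relevant channels", {
  base <- list(duration_s = 15, rate_jitter_cpm = 0, depth_jitter_mm = 0,
               release_jitter_mm = 0, sensor_noise_sd = 0, seed = 9)
  locked <- do.call(simulation_params, c(base, arms_locked = TRUE))
  loose <- do.call(simulation_params, c(base, arms_locked = FALSE))
  fa <- simulate_session(locked)$session$sensor_recordings$Kinect$frames
  fb <- simulate_session(loose)$session$sensor_recordings$Kinect$frames
  expect_gt(mean(abs(fa$Kinect.ElbowLeftY - fb$Kinect.ElbowLeftY)), 0)
  expect_equal(fa$Kinect.HandLeftY, fb$Kinect.HandLeftY)  # hands unaffected

  wbody <- do.call(simulation_params, c(base, body_weight = TRUE))
  nbody <- do.call(simulation_params, c(base, body_weight = FALSE))
  sa <- simulate_session(wbody)$session
  sb <- simulate_session(nbody)$session
  expect_gt(mean(abs(sa$sensor_recordings$Kinect$frames$Kinect.ShoulderLeftY -
                     sb$sensor_recordings$Kinect$frames$Kinect.ShoulderLeftY)),
            0)
  expect_gt(mean(sb$sensor_recordings$Myo$frames$Myo.EMGPod0),
            mean(sa$sensor_recordings$Myo$frames$Myo.EMGPod0))
})

test_that("emulated measurements reproduce intended classes across mistakes", {
  # parameters sit >= 2 jitter SDs inside/outside the guideline intervals;
  # the emulator plays the manikin, which feels the true displacement, so the
  # camera noise channel is off here (per-compression jitter stays on)
  cases <- data.frame(rate = c(80, 110, 130), depth = c(40, 55, 65),
                      release = c(2, 10, 2),
                      classRate = c(0L, 1L, 2L), classDepth = c(0L, 1L, 2L),
                      classRelease = c(1L, 0L, 1L))
  for (i in seq_len(nrow(cases))) {
    p <- simulation_params(rate_cpm = cases$rate[i],
                           depth_mm = cases$depth[i],
                           release_mm = cases$release[i],
                           sensor_noise_sd = 0,
                           duration_s = 15, seed = 40 + i)
    sim <- simulate_session(p)
    gt <- sim$ground_truth
    tr <- extract_displacement(sim$session)
    em <- manikin_emulate(tr$displacement_mm, tr$time,
                          c(gt$start, gt$end[nrow(gt)]))
    lab <- label_compressions(em)
    # labels derived from emulated measurements agree with labels derived
    # from the generator's true values (exact except hairline boundary draws)
    gl <- label_compressions(gt[c("compDepth", "compMeanRate", "compRelease")])
    expect_gt(mean(lab$classRate == gl$classRate), 0.99)
    expect_gt(mean(lab$classDepth == gl$classDepth), 0.99)
    expect_gt(mean(lab$classRelease == gl$classRelease), 0.99)
    # and mostly reproduce the intended (target-parameter) class
    expect_true(mean(lab$classRate == cases$classRate[i]) > 0.9,
                label = paste("rate class, case", i))
    expect_true(mean(lab$classDepth == cases$classDepth[i]) > 0.9,
                label = paste("depth class, case", i))
    expect_true(mean(lab$classRelease == cases$classRelease[i]) > 0.9,
                label = paste("release class, case", i))
  }
})

test_that("cohort generation is deterministic and spans the levels", {
  a <- simulate_cohort(n_sessions = 6, duration_s = 10, seed = 2)
  b <- simulate_cohort(n_sessions = 6, duration_s = 10, seed = 2)
  expect_identical(lapply(a, `[[`, "rate_cpm"), lapply(b, `[[`, "rate_cpm"))
  expect_length(a, 6)
  expect_true(all(vapply(a, inherits, TRUE, "simulation_params")))
})
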