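# Synthetic CPR sessions with known ground truth.
#
# The kinematic model is deliberately simple and fully documented (see the
# methods vignette): each compression cycle is a raised-cosine displacement
# pulse whose peak is the compression depth and whose baseline is the residual
# release depth. Skeleton joints, EMG bursts and inertial channels are derived
# from that pulse, sampled at per-device rates with additive Gaussian noise.

#' Constants of the synthetic kinematic model
#'
#' Every constant of the signal model is named here rather than hard-coded:
#' `alpha_body` / `alpha_no_body` scale how much the shoulders and spine move
#' with the hands (trunk-driven vs arm-driven compressions); `elbow_dip`
#' is the extra elbow excursion (fraction of the pulse) when the arms are not
#' locked; `emg_amp` is the EMG burst amplitude (a.u.) and
#' `emg_no_body_gain` the arm-muscle compensation factor when body weight is
#' not used; `emg_burst_width` is the burst SD as a fraction of the cycle;
#' `emg_noise_scale`, `imu_noise_scale` convert the skeleton-space noise SD
#' (metres) into EMG / inertial channel units; `arm_length_m` converts hand
#' velocity into a forearm angular rate.
#'
#' @param alpha_body,alpha_no_body,elbow_dip,emg_amp,emg_no_body_gain,emg_burst_width,emg_noise_scale,imu_noise_scale,arm_length_m
#'   see description.
#' @return named list of constants.
#' @export
cpr_model_constants <- function(alpha_body = 1, alpha_no_body = 0.3,
                                elbow_dip = 0.25, emg_amp = 30,
                                emg_no_body_gain = 2, emg_burst_width = 0.15,
                                emg_noise_scale = 400, imu_noise_scale = 20,
                                arm_length_m = 0.3) {
  as.list(environment())
}

#' Simulation parameters for a synthetic CPR session
#'
#' Defaults emulate a guideline-correct two-minute compression-only session:
#' 110 compressions/min, 55 mm deep, 2 mm residual release, arms locked, body
#' weight used. Per-compression Gaussian jitters model human variability;
#' `sensor_noise_sd` is the additive channel noise in skeleton units (metres),
#' scaled into the other devices' units via [cpr_model_constants()].
#'
#' @param rate_cpm target compression rate, compressions/min.
#' @param depth_mm target compression depth, mm.
#' @param release_mm target residual depth at release, mm.
#' @param arms_locked logical: elbows locked (shoulder-elbow-hand collinear).
#' @param body_weight logical: trunk mass used (shoulders follow the hands).
#' @param duration_s length of the compression phase in seconds.
#' @param lead_in_s rest period before the first compression (chest fully
#'   released), giving downstream baseline estimation a reference; the
#'   recording also continues for the same time after the last compression,
#'   so the final release is observed. The total trace spans
#'   `duration_s + 2 * lead_in_s`.
#' @param rate_jitter_cpm,depth_jitter_mm,release_jitter_mm per-compression
#'   Gaussian SDs.
#' @param sensor_noise_sd additive Gaussian noise SD, metres.
#' @param kinect_hz,myo_hz device sampling rates, Hz.
#' @param seed RNG seed (`NULL` = leave the RNG alone).
#' @param constants a [cpr_model_constants()] list.
#' @return object of class `simulation_params`.
#' @export
simulation_params <- function(rate_cpm = 110, depth_mm = 55, release_mm = 2,
                              arms_locked = TRUE, body_weight = TRUE,
                              duration_s = 120, lead_in_s = 1,
                              rate_jitter_cpm = 3,
                              depth_jitter_mm = 2, release_jitter_mm = 1,
                              sensor_noise_sd = 0.005,
                              kinect_hz = 30, myo_hz = 100, seed = NULL,
                              constants = cpr_model_constants()) {
  stopifnot(rate_cpm > 0, depth_mm > 0, duration_s > 0, release_mm >= 0,
            lead_in_s >= 0, rate_jitter_cpm >= 0, depth_jitter_mm >= 0,
            release_jitter_mm >= 0, sensor_noise_sd >= 0,
            kinect_hz > 0, myo_hz > 0,
            is.logical(arms_locked), is.logical(body_weight))
  structure(as.list(environment()), class = "simulation_params")
}

# 15-joint Kinect skeleton: rest positions in metres, Kinect camera frame
# (magnitudes matching real recordings: Z ~ 2 m from the camera).
.kinect_joints <- function() {
  data.frame(
    joint = c("Head", "SpineShoulder", "SpineMid",
              "ShoulderLeft", "ShoulderRight", "ElbowLeft", "ElbowRight",
              "WristLeft", "WristRight", "HandLeft", "HandRight",
              "HipLeft", "HipRight", "AnkleLeft", "AnkleRight"),
    x = c(0.02, 0.01, 0.01, -0.17, 0.19, -0.35, 0.37, -0.51, 0.53,
          -0.52, 0.54, -0.12, 0.14, -0.15, 0.17),
    y = c(0.95, 0.78, 0.55, 0.72, 0.72, 0.51, 0.51, 0.33, 0.33,
          0.30, 0.30, 0.22, 0.22, -0.45, -0.45),
    z = c(2.00, 2.02, 2.05, 2.03, 2.03, 1.98, 1.98, 1.92, 1.92,
          1.90, 1.90, 2.10, 2.10, 2.35, 2.35),
    stringsAsFactors = FALSE
  )
}

# Displacement (mm, >= 0, downward positive) at times t for a cycle table with
# columns start, end, depth, release. Outside all cycles the chest rests at
# the adjacent cycle's release level (0 before the first cycle).
.displacement <- function(t, cycles) {
  d <- numeric(length(t))
  if (!nrow(cycles)) return(d)
  idx <- findInterval(t, cycles$start)
  inside <- idx >= 1L
  ii <- idx[inside]
  u <- (t[inside] - cycles$start[ii]) / (cycles$end[ii] - cycles$start[ii])
  rel <- cycles$release[ii]
  dep <- cycles$depth[ii]
  val <- rel + (dep - rel) * (1 - cos(2 * pi * pmin(u, 1))) / 2
  past_end <- u > 1  # after the last cycle ends
  val[past_end] <- rel[past_end]
  d[inside] <- val
  d
}

#' Simulate a multimodal CPR session with known ground truth
#'
#' Draws per-compression rate/depth/release around the targets, builds the
#' raised-cosine displacement trace, derives skeleton (15 joints x X/Y/Z at
#' `kinect_hz`), EMG + inertial channels (18 attributes at `myo_hz`), and
#' packs everything into a valid [mlt_session()]. The ground truth holds one
#' [annotation_recording()]-style interval per compression with the true
#' `compDepth`, `compMeanRate`, `compRelease` and the generating
#' `armsLocked` / `bodyWeight` flags.
#'
#' Signal roles: hand and wrist Y track the (negated) displacement; shoulders
#' and spine track `-alpha * d(t)` with `alpha = alpha_body` when body weight
#' is used, else `alpha_no_body`; elbows stay collinear between shoulder and
#' hand when arms are locked, else dip an extra `elbow_dip * d(t)`; each EMG
#' channel emits one rectified burst per cycle, amplified by
#' `emg_no_body_gain` when body weight is not used; the accelerometer is the
#' discrete second derivative of the hand trajectory, the gyroscope the first
#' derivative mapped through the forearm length, and the orientation tilts
#' with the displacement.
#'
#' @param params a [simulation_params()].
#' @param session_id identifier for the generated session.
#' @param recording_datetime absolute session date-time.
#' @return list of class `cpr_simulation` with elements `session`
#'   ([mlt_session()]) and `ground_truth` (data.frame: `start`, `end`,
#'   `compDepth`, `compMeanRate`, `compRelease`, `armsLocked`, `bodyWeight`).
#' @export
simulate_session <- function(params = simulation_params(),
                             session_id = "simulated-session",
                             recording_datetime =
                               as.POSIXct("2019-01-01 00:00:00", tz = "UTC")) {
  stopifnot(inherits(params, "simulation_params"))
  p <- params
  k <- p$constants
  if (!is.null(p$seed)) set.seed(p$seed)
  if (p$duration_s < 60 / p$rate_cpm) {
    stop("duration_s too short for a single compression cycle", call. = FALSE)
  }

  # --- per-compression ground truth ---------------------------------------
  starts <- numeric(0); rates <- numeric(0)
  depths <- numeric(0); rels <- numeric(0)
  t0 <- p$lead_in_s
  t_end <- p$lead_in_s + p$duration_s
  repeat {
    r <- max(30, p$rate_cpm + stats::rnorm(1, 0, p$rate_jitter_cpm))
    period <- 60 / r
    if (t0 + period > t_end + 1e-9) break
    starts <- c(starts, t0)
    rates <- c(rates, r)
    d <- max(10, p$depth_mm + stats::rnorm(1, 0, p$depth_jitter_mm))
    depths <- c(depths, d)
    rel <- min(0.5 * d,
               max(0, p$release_mm + stats::rnorm(1, 0, p$release_jitter_mm)))
    rels <- c(rels, rel)
    t0 <- t0 + period
  }
  cycles <- data.frame(start = starts, end = starts + 60 / rates,
                       depth = depths, release = rels)
  ground_truth <- data.frame(
    start = cycles$start, end = cycles$end,
    compDepth = cycles$depth, compMeanRate = rates,
    compRelease = cycles$release,
    armsLocked = as.integer(p$arms_locked),
    bodyWeight = as.integer(p$body_weight)
  )

  alpha <- if (p$body_weight) k$alpha_body else k$alpha_no_body
  noise <- function(n) stats::rnorm(n, 0, p$sensor_noise_sd)

  # --- Kinect stream ------------------------------------------------------
  t_trace <- t_end + p$lead_in_s + 1 / p$kinect_hz
  tk <- seq(0, t_trace, by = 1 / p$kinect_hz)
  dm <- .displacement(tk, cycles) / 1000  # metres
  joints <- .kinect_joints()
  nk <- length(tk)
  kin <- data.frame(timestamp = tk)
  for (j in seq_len(nrow(joints))) {
    jn <- joints$joint[j]
    dy <- switch(
      jn,
      HandLeft = , HandRight = , WristLeft = , WristRight = -dm,
      ShoulderLeft = , ShoulderRight = , SpineShoulder = ,
      SpineMid = -alpha * dm,
      ElbowLeft = , ElbowRight = {
        mid <- -(1 + alpha) / 2 * dm  # collinear shoulder-hand midpoint
        if (p$arms_locked) mid else mid - k$elbow_dip * dm
      },
      numeric(nk)  # Head, Hips, Ankles: static
    )
    kin[[paste0("Kinect.", jn, "X")]] <- joints$x[j] + noise(nk)
    kin[[paste0("Kinect.", jn, "Y")]] <- joints$y[j] + dy + noise(nk)
    kin[[paste0("Kinect.", jn, "Z")]] <- joints$z[j] + noise(nk)
  }

  # --- Myo stream (8 EMG + accelerometer, gyroscope, orientation) ---------
  tm <- seq(0, t_trace, by = 1 / p$myo_hz)
  nm <- length(tm)
  dmm <- .displacement(tm, cycles)          # mm
  ym <- -dmm / 1000                         # hand height, metres
  dt <- 1 / p$myo_hz
  vel <- c(0, diff(ym)) / dt                # m/s
  acc <- c(0, diff(vel)) / dt / 9.81        # g
  # burst phase: distance of cycle phase from mid-compression
  idx <- findInterval(tm, cycles$start)
  u <- rep(NA_real_, nm)
  ok <- idx >= 1L
  u[ok] <- (tm[ok] - cycles$start[idx[ok]]) /
    (cycles$end[idx[ok]] - cycles$start[idx[ok]])
  u[!ok | u > 1] <- NA
  burst <- exp(-((u - 0.5)^2) / (2 * k$emg_burst_width^2))
  burst[is.na(burst)] <- 0
  emg_gain <- if (p$body_weight) 1 else k$emg_no_body_gain
  ch_gain <- seq(0.6, 1.3, length.out = 8)
  myo <- data.frame(timestamp = tm)
  mnoise <- function(scale) stats::rnorm(nm, 0, p$sensor_noise_sd * scale)
  for (ch in 0:7) {
    myo[[paste0("Myo.EMGPod", ch)]] <-
      k$emg_amp * emg_gain * ch_gain[ch + 1] * burst + mnoise(k$emg_noise_scale)
  }
  myo[["Myo.AccX"]] <- 0.05 + mnoise(k$imu_noise_scale)
  myo[["Myo.AccY"]] <- acc + mnoise(k$imu_noise_scale)
  myo[["Myo.AccZ"]] <- -0.98 + mnoise(k$imu_noise_scale)
  gyr <- vel / k$arm_length_m * 180 / pi    # deg/s
  myo[["Myo.GyrX"]] <- gyr + mnoise(k$imu_noise_scale)
  myo[["Myo.GyrY"]] <- mnoise(k$imu_noise_scale)
  myo[["Myo.GyrZ"]] <- mnoise(k$imu_noise_scale)
  myo[["Myo.OriX"]] <- 0.10 + mnoise(k$imu_noise_scale / 100)
  myo[["Myo.OriY"]] <- -0.19 + 0.5 * dmm / 1000 + mnoise(k$imu_noise_scale / 100)
  myo[["Myo.OriZ"]] <- 0.05 + mnoise(k$imu_noise_scale / 100)
  myo[["Myo.OriW"]] <- 0.97 + mnoise(k$imu_noise_scale / 100)

  session <- mlt_session(
    session_id,
    sensor_recordings = list(sensor_recording("Kinect", kin),
                             sensor_recording("Myo", myo)),
    annotation_recordings = list(
      annotation_recording("Annotation", ground_truth)),
    recording_datetime = recording_datetime
  )
  structure(list(session = session, ground_truth = ground_truth,
                 params = params),
            class = "cpr_simulation")
}

#' Parameter sets for a labelled cohort of simulated sessions
#'
#' Draws one [simulation_params()] per session, with rate, depth, release,
#' arm locking and body-weight use sampled independently from mistake levels
#' that sit at least two jitter SDs inside or outside the guideline
#' intervals, so the intended class of every compression is (with
#' overwhelming probability) the labelled class. This is the package's
#' stand-in for a multi-participant training cohort: each "participant" is a
#' parameter setting.
#'
#' @param n_sessions number of sessions.
#' @param duration_s compression time per session.
#' @param seed cohort seed (per-session seeds derive from it).
#' @param rates,depths,releases candidate target levels (compressions/min,
#'   mm, mm), spanning the too-low / correct / too-high classes.
#' @param ... further arguments forwarded to [simulation_params()]
#'   (jitters, noise, sampling rates).
#' @return list of [simulation_params()].
#' @export
simulate_cohort <- function(n_sessions = 16, duration_s = 60, seed = 1,
                            rates = c(80, 110, 130),
                            depths = c(40, 55, 65),
                            releases = c(2, 10), ...) {
  stopifnot(n_sessions >= 1)
  set.seed(seed)
  lapply(seq_len(n_sessions), function(i) {
    simulation_params(
      rate_cpm = sample(rates, 1),
      depth_mm = sample(depths, 1),
      release_mm = sample(releases, 1),
      arms_locked = sample(c(TRUE, FALSE), 1),
      body_weight = sample(c(TRUE, FALSE), 1),
      duration_s = duration_s,
      seed = (seed * 1009L + i) %% 2147483647L,
      ...)
  })
}

#' Derive per-compression manikin measurements from a displacement trace
#'
#' Emulates what a training manikin reports: for each cycle, the peak downward
#' displacement (`compDepth`, mm), the mean rate from the cycle period
#' (`compMeanRate`, compressions/min) and the minimum displacement between the
#' peak and the next compression onset (`compRelease`, mm). The trace is
#' first upsampled to a 1 ms grid with a cubic spline, so extrema recovery is
#' accurate well below the device sampling interval (interpolation error
#' ~0.01 mm for a 30 Hz skeleton stream at guideline rates).
#'
#' @param displacement_mm numeric vector, downward chest displacement in mm.
#' @param times numeric vector of sample times (seconds), same length.
#' @param cycle_boundaries numeric vector of cycle onset times, length
#'   `n_cycles + 1` (the last entry closes the final cycle).
#' @return data.frame with one row per complete cycle: `start`, `end`,
#'   `compDepth`, `compMeanRate`, `compRelease`. Zero rows when fewer than
#'   one full cycle is covered.
#' @export
manikin_emulate <- function(displacement_mm, times, cycle_boundaries) {
  stopifnot(length(displacement_mm) == length(times))
  b <- sort(cycle_boundaries)
  ncyc <- length(b) - 1L
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      compDepth = numeric(0), compMeanRate = numeric(0),
                      compRelease = numeric(0))
  if (ncyc < 1L || !length(times)) return(empty)

  keep <- !duplicated(times)
  ord <- order(times[keep])
  tt <- times[keep][ord]
  dd <- displacement_mm[keep][ord]
  if (length(tt) >= 4L) {
    fine <- stats::spline(tt, dd, xout = seq(min(tt), max(tt), by = 0.001))
    tt <- fine$x
    dd <- fine$y
  }

  rows <- vector("list", ncyc)
  for (c_i in seq_len(ncyc)) {
    sel <- which(tt >= b[c_i] & tt < b[c_i + 1L])
    if (!length(sel)) next
    ipk <- sel[which.max(dd[sel])]
    post <- sel[sel >= ipk]
    rows[[c_i]] <- data.frame(
      start = b[c_i], end = b[c_i + 1L],
      compDepth = dd[ipk],
      compMeanRate = 60 / (b[c_i + 1L] - b[c_i]),
      compRelease = max(0, min(dd[post])))
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Extract a displacement trace (mm) from a simulated or recorded session
#'
#' Converts a vertical joint coordinate stream (default: left hand Y, metres)
#' into downward displacement in mm relative to its resting level, estimated
#' as the maximum (least-compressed) observed height.
#'
#' @param session an [mlt_session()].
#' @param recording name of the sensor recording (default `"Kinect"`).
#' @param attribute channel to use.
#' @return data.frame with `time` (s) and `displacement_mm`.
#' @export
extract_displacement <- function(session, recording = "Kinect",
                                 attribute = "Kinect.HandLeftY") {
  rec <- session$sensor_recordings[[recording]]
  if (is.null(rec)) stop("no sensor recording named ", recording, call. = FALSE)
  if (!attribute %in% names(rec$frames)) {
    stop("no attribute ", attribute, " in recording ", recording,
         call. = FALSE)
  }
  y <- rec$frames[[attribute]]
  data.frame(time = rec$frames$timestamp,
             displacement_mm = (max(y) - y) * 1000)
}
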