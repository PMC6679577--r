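# Shared fixtures (all generated in code) and independent oracles.

# A small deterministic session with two sensor streams and one annotation
# recording; `seed` varies the attribute values.
make_toy_session <- function(seed = 1, n_frames = 40, id = "toy") {
  set.seed(seed)
  kin <- data.frame(timestamp = seq(0, by = 1 / 30, length.out = n_frames),
                    Kinect.HandLeftY = rnorm(n_frames, 0.3, 0.01),
                    Kinect.HeadZ = rnorm(n_frames, 2, 0.01))
  myo <- data.frame(timestamp = seq(0, by = 1 / 100,
                                    length.out = 3 * n_frames),
                    Myo.EMGPod0 = rnorm(3 * n_frames, 0, 5),
                    Myo.AccY = rnorm(3 * n_frames, -1, 0.1))
  ann <- data.frame(start = c(0.1, 0.75), end = c(0.7, 1.2),
                    compDepth = c(55, 61), compMeanRate = c(110, 95),
                    compRelease = c(3, 7))
  mlt_session(id,
              sensor_recordings = list(sensor_recording("Kinect", kin),
                                       sensor_recording("Myo", myo)),
              annotation_recordings = list(
                annotation_recording("Annotation", ann)))
}

# Independent brute-force resampling oracle: walks every raw sample, assigns
# it to a bin by explicit edge comparison, averages, then linearly
# interpolates empty bins (nearest-value extension at the edges). Kept
# deliberately loop-based and separate from the implementation under test.
oracle_resample <- function(times, values, start, end, S) {
  edges <- seq(start, end, length.out = S + 1)
  sums <- numeric(S)
  counts <- numeric(S)
  for (i in seq_along(times)) {
    if (is.na(values[i])) next
    for (b in seq_len(S)) {
      in_bin <- times[i] >= edges[b] &&
        (times[i] < edges[b + 1] || (b == S && times[i] < end))
      if (in_bin) {
        sums[b] <- sums[b] + values[i]
        counts[b] <- counts[b] + 1
        break
      }
    }
  }
  out <- ifelse(counts > 0, sums / counts, NA_real_)
  good <- which(!is.na(out))
  if (!length(good)) return(rep(NA_real_, S))
  for (b in seq_len(S)) {
    if (!is.na(out[b])) next
    lo <- good[good < b]
    hi <- good[good > b]
    if (!length(lo)) {
      out[b] <- out[min(hi)]
    } else if (!length(hi)) {
      out[b] <- out[max(lo)]
    } else {
      l <- max(lo); h <- min(hi)
      out[b] <- out[l] + (out[h] - out[l]) * (b - l) / (h - l)
    }
  }
  out
}

# Quick flag columns for per-test bin emptiness checks
oracle_bin_counts <- function(times, start, end, S) {
  edges <- seq(start, end, length.out = S + 1)
  counts <- integer(S)
  for (t in times) {
    for (b in seq_len(S)) {
      if (t >= edges[b] && (t < edges[b + 1] || (b == S && t < end))) {
        counts[b] <- counts[b] + 1L
        break
      }
    }
  }
  counts
}
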