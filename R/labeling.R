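# Guideline-based labelling of per-compression manikin measurements.
#
# Rate and depth are ternary: 0 = below the guideline interval, 1 = within
# (bounds inclusive), 2 = above. Release is binary: 1 = fully released
# (residual depth at or under the threshold), 0 = incomplete release. Arm
# locking and body-weight use have no instrumented measurement and are only
# validated/propagated.

#' Guideline thresholds for compression quality
#'
#' Defaults follow the European resuscitation guidelines: rate 100-120
#' compressions/min, depth 50-60 mm, both inclusive at the bounds. The
#' release threshold defaults to 5 mm residual depth, the conventional
#' training-manikin cutoff for "complete release".
#'
#' @param rate_interval numeric length-2, compressions/min, `low < high`.
#' @param depth_interval numeric length-2, mm, `low < high`.
#' @param release_max maximum residual depth (mm) still counted as released.
#' @return object of class `guideline_thresholds`.
#' @export
guideline_thresholds <- function(rate_interval = c(100, 120),
                                 depth_interval = c(50, 60),
                                 release_max = 5) {
  stopifnot(length(rate_interval) == 2L, length(depth_interval) == 2L,
            is.numeric(rate_interval), is.numeric(depth_interval),
            is.numeric(release_max), length(release_max) == 1L)
  if (rate_interval[1] > rate_interval[2]) {
    stop("rate_interval must satisfy low <= high", call. = FALSE)
  }
  if (depth_interval[1] > depth_interval[2]) {
    stop("depth_interval must satisfy low <= high", call. = FALSE)
  }
  if (release_max <= 0) stop("release_max must be > 0", call. = FALSE)
  structure(list(rate_interval = as.numeric(rate_interval),
                 depth_interval = as.numeric(depth_interval),
                 release_max = as.numeric(release_max)),
            class = "guideline_thresholds")
}

.label_interval <- function(x, low, high) {
  ifelse(x < low, 0L, ifelse(x <= high, 1L, 2L))
}

#' Classify compression rate against the guideline interval
#'
#' @param comp_mean_rate numeric vector, compressions/min, strictly positive.
#' @param thresholds a [guideline_thresholds()].
#' @return integer vector in {0, 1, 2}: too slow / on point / too fast.
#' @examples
#' th <- guideline_thresholds()
#' label_rate(c(98, 110, 121), th)  # 0 1 2
#' @export
label_rate <- function(comp_mean_rate, thresholds = guideline_thresholds()) {
  stopifnot(inherits(thresholds, "guideline_thresholds"))
  if (any(is.na(comp_mean_rate)) || any(comp_mean_rate <= 0)) {
    stop("compression rate must be > 0", call. = FALSE)
  }
  .label_interval(comp_mean_rate, thresholds$rate_interval[1],
                  thresholds$rate_interval[2])
}

#' Classify compression depth against the guideline interval
#'
#' @param comp_depth_mm numeric vector, mm, non-negative.
#' @inheritParams label_rate
#' @return integer vector in {0, 1, 2}: too shallow / on point / too deep.
#' @export
label_depth <- function(comp_depth_mm, thresholds = guideline_thresholds()) {
  stopifnot(inherits(thresholds, "guideline_thresholds"))
  if (any(is.na(comp_depth_mm)) || any(comp_depth_mm < 0)) {
    stop("compression depth must be >= 0", call. = FALSE)
  }
  .label_interval(comp_depth_mm, thresholds$depth_interval[1],
                  thresholds$depth_interval[2])
}

#' Classify compression release
#'
#' @param comp_release_mm residual depth at release, mm, non-negative.
#' @inheritParams label_rate
#' @return integer vector in {0, 1}: 1 = fully released, 0 = not.
#' @export
label_release <- function(comp_release_mm,
                          thresholds = guideline_thresholds()) {
  stopifnot(inherits(thresholds, "guideline_thresholds"))
  if (any(is.na(comp_release_mm)) || any(comp_release_mm < 0)) {
    stop("release residual must be >= 0", call. = FALSE)
  }
  ifelse(comp_release_mm <= thresholds$release_max, 1L, 0L)
}

#' Attach guideline class labels to compression intervals
#'
#' Derives `classRate`, `classDepth` and `classRelease` from the
#' `compMeanRate`, `compDepth` and `compRelease` measurement columns. Label
#' columns already present in the input (including the human-annotated
#' `armsLocked` / `bodyWeight`) are passed through untouched and never
#' recomputed.
#'
#' @param intervals data.frame of compression intervals (or an
#'   [annotation_recording()]) with measurement columns.
#' @param thresholds a [guideline_thresholds()].
#' @param targets which labels to derive; default: every derivable label not
#'   already present.
#' @return input with label columns attached (same class as the input).
#' @export
label_compressions <- function(intervals,
                               thresholds = guideline_thresholds(),
                               targets = NULL) {
  if (inherits(intervals, "annotation_recording")) {
    intervals$intervals <-
      label_compressions(intervals$intervals, thresholds, targets)
    return(intervals)
  }
  intervals <- as.data.frame(intervals)
  needed <- c(classRate = "compMeanRate", classDepth = "compDepth",
              classRelease = "compRelease")
  if (is.null(targets)) {
    targets <- setdiff(names(needed), names(intervals))
    targets <- targets[needed[targets] %in% names(intervals)]
  } else {
    targets <- setdiff(targets, names(intervals))  # existing labels untouched
    bad <- setdiff(targets, names(needed))
    if (length(bad)) {
      stop("no measurement rule for label(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    missing_meas <- needed[targets][!(needed[targets] %in% names(intervals))]
    if (length(missing_meas)) {
      stop("missing measurement column(s): ",
           paste(missing_meas, collapse = ", "), call. = FALSE)
    }
  }
  if (nrow(intervals) == 0L) return(intervals)
  for (tg in targets) {
    intervals[[tg]] <- switch(
      tg,
      classRate = label_rate(intervals$compMeanRate, thresholds),
      classDepth = label_depth(intervals$compDepth, thresholds),
      classRelease = label_release(intervals$compRelease, thresholds)
    )
  }
  intervals
}
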