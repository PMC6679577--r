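# From raw recordings to a fixed-shape feature tensor:
#   interval table -> consolidated attribute table -> per-interval masking ->
#   fixed-size bin resampling (S bins per compression) -> N x S x Q tensor
#   with per-attribute [0,1] min-max scaling.

#' Stack annotation intervals from one or more sessions into one table
#'
#' Computes each interval's duration (`end - start`) and anchors relative
#' times on the absolute session date-time (`abs_start`), so intervals from
#' different sessions sharing t0 = 0 stay distinguishable when stacked.
#'
#' @param x an [mlt_session()], a list of sessions, or a list of
#'   [annotation_recording()]s (then `datetimes` supplies one `POSIXct` per
#'   recording).
#' @param datetimes optional `POSIXct` vector, one per annotation recording;
#'   ignored when `x` carries sessions.
#' @return data.frame of class `interval_table`: `session_id`, `start`,
#'   `end`, `duration`, `abs_start`, plus every measurement/label column
#'   found in the annotations.
#' @export
build_interval_table <- function(x, datetimes = NULL) {
  if (inherits(x, "mlt_session")) x <- list(x)
  pieces <- list()
  for (i in seq_along(x)) {
    el <- x[[i]]
    if (inherits(el, "mlt_session")) {
      recs <- el$annotation_recordings
      dt <- el$recording_datetime
      sid <- el$session_id
    } else if (inherits(el, "annotation_recording")) {
      recs <- list(el)
      dt <- if (is.null(datetimes)) {
        as.POSIXct("2019-01-01 00:00:00", tz = "UTC")
      } else {
        datetimes[i]
      }
      sid <- el$application_name
    } else {
      stop("expected mlt_session or annotation_recording elements",
           call. = FALSE)
    }
    for (rec in recs) {
      iv <- rec$intervals
      if (!nrow(iv)) next
      if (rec$time_offset != 0) {
        iv$start <- iv$start + rec$time_offset
        iv$end <- iv$end + rec$time_offset
      }
      bad <- which(iv$end <= iv$start)
      if (length(bad)) {
        stop("interval(s) with end <= start in ", sid, " at row(s) ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      iv <- iv[order(iv$start), , drop = FALSE]
      base <- data.frame(session_id = sid, start = iv$start, end = iv$end,
                         duration = iv$end - iv$start,
                         abs_start = dt + iv$start,
                         stringsAsFactors = FALSE)
      pieces[[length(pieces) + 1L]] <-
        cbind(base, iv[setdiff(names(iv), c("start", "end"))])
    }
  }
  if (!length(pieces)) {
    out <- data.frame(session_id = character(0), start = numeric(0),
                      end = numeric(0), duration = numeric(0),
                      abs_start = as.POSIXct(character(0), tz = "UTC"))
  } else {
    out <- as.data.frame(data.table::rbindlist(pieces, fill = TRUE))
  }
  class(out) <- c("interval_table", "data.frame")
  out
}

#' Consolidate sensor recordings into one time-indexed attribute table
#'
#' Per recording: sanitises attribute names (underscores and other special
#' characters removed), applies the recording's time offset, and drops rows
#' duplicating an earlier timestamp (keep-first). The streams are then
#' concatenated into one table sorted by timestamp: rows are sensor updates,
#' columns the union of attributes, with `NA` where a device did not update
#' (missing means absent, not zero, so later bin means are not corrupted).
#' Columns whose running total is zero (uninformative) and columns matching an
#' excluded joint name are discarded.
#'
#' @param sensor_recordings a [sensor_recording()], a list of them, or an
#'   [mlt_session()] (its sensor recordings are used).
#' @param excluded_joints character vector of substrings; any attribute whose
#'   name contains one is dropped. Default: ankles, hips and head, which do
#'   not inform compression quality (kneeling performer; head looks around).
#' @return data.frame of class `attribute_table`: `timestamp` plus surviving
#'   attribute columns, strictly increasing timestamps within each source
#'   recording's contribution.
#' @export
build_attribute_table <- function(sensor_recordings,
                                  excluded_joints = c("Ankle", "Hip", "Head")) {
  if (inherits(sensor_recordings, "mlt_session")) {
    sensor_recordings <- sensor_recordings$sensor_recordings
  }
  if (inherits(sensor_recordings, "sensor_recording")) {
    sensor_recordings <- list(sensor_recordings)
  }
  if (!length(sensor_recordings)) {
    stop("need at least one sensor recording", call. = FALSE)
  }
  pieces <- list()
  for (rec in sensor_recordings) {
    stopifnot(inherits(rec, "sensor_recording"))
    fr <- rec$frames
    if (!nrow(fr)) next
    attrs <- setdiff(names(fr), "timestamp")
    clean <- gsub("[^A-Za-z0-9]", "", attrs)
    if (anyDuplicated(clean)) {
      stop("attribute names collide after sanitisation in ",
           rec$application_name, call. = FALSE)
    }
    names(fr)[match(attrs, names(fr))] <- clean
    if (rec$time_offset != 0) fr$timestamp <- fr$timestamp + rec$time_offset
    fr <- fr[!duplicated(fr$timestamp), , drop = FALSE]
    pieces[[length(pieces) + 1L]] <- fr
  }
  if (!length(pieces)) stop("all sensor recordings are empty", call. = FALSE)
  tab <- as.data.frame(data.table::rbindlist(pieces, fill = TRUE))
  tab <- tab[order(tab$timestamp), , drop = FALSE]
  rownames(tab) <- NULL

  attrs <- setdiff(names(tab), "timestamp")
  drop_excl <- attrs[vapply(attrs, function(a) {
    any(vapply(excluded_joints, grepl, TRUE, x = a, fixed = TRUE))
  }, TRUE)]
  drop_zero <- attrs[vapply(attrs, function(a) {
    s <- sum(tab[[a]], na.rm = TRUE)
    s == 0
  }, TRUE)]
  keep <- setdiff(attrs, union(drop_excl, drop_zero))
  if (!length(keep)) {
    stop("no attributes survive pruning: nothing to learn from",
         call. = FALSE)
  }
  tab <- tab[, c("timestamp", keep), drop = FALSE]
  class(tab) <- c("attribute_table", "data.frame")
  attr(tab, "dropped_excluded") <- drop_excl
  attr(tab, "dropped_zero") <- drop_zero
  tab
}

#' Export the attribute table densely (absent updates as zeros)
#'
#' @param attribute_table an [build_attribute_table()] result.
#' @return data.frame with `NA` replaced by 0.
#' @export
as_dense_attribute_table <- function(attribute_table) {
  out <- as.data.frame(attribute_table)
  out[is.na(out)] <- 0
  out
}

#' Mask the attribute table with compression intervals
#'
#' One masked series per interval: exactly the sensor updates with
#' `start <= t < end` (half-open, so a boundary update belongs to one
#' compression only). Intervals must not overlap; this is verified.
#'
#' @param attribute_table from [build_attribute_table()].
#' @param interval_table from [build_interval_table()] (or any data.frame
#'   with `start`/`end` on the same time base as the attribute table).
#' @return list of class `masked_series_list`; each element has `start`,
#'   `end`, `times`, and `values` (matrix: updates x attributes, `NA` where a
#'   device did not update). Elements with zero updates are flagged with
#'   attribute `empty = TRUE` and counted in a warning.
#' @export
mask_by_intervals <- function(attribute_table, interval_table) {
  iv <- as.data.frame(interval_table)
  stopifnot(all(c("start", "end") %in% names(iv)))
  iv <- iv[order(iv$start), , drop = FALSE]
  if (nrow(iv) > 1L && any(iv$start[-1L] < iv$end[-nrow(iv)] - 1e-9)) {
    stop("intervals overlap: masking would assign updates twice",
         call. = FALSE)
  }
  ts <- attribute_table$timestamp
  vals <- as.matrix(attribute_table[setdiff(names(attribute_table),
                                            "timestamp")])
  # ts is sorted; locate [start, end) slices by binary search
  lo <- findInterval(iv$start, ts, left.open = TRUE) + 1L  # first t >= start
  hi <- findInterval(iv$end, ts, left.open = TRUE)         # last t < end
  out <- vector("list", nrow(iv))
  n_empty <- 0L
  for (i in seq_len(nrow(iv))) {
    sel <- if (lo[i] <= hi[i]) lo[i]:hi[i] else integer(0)
    m <- list(start = iv$start[i], end = iv$end[i],
              times = ts[sel],
              values = vals[sel, , drop = FALSE])
    if (!length(sel)) {
      attr(m, "empty") <- TRUE
      n_empty <- n_empty + 1L
    }
    out[[i]] <- m
  }
  if (n_empty) {
    warning(n_empty, " interval(s) contain no sensor updates", call. = FALSE)
  }
  structure(out, class = "masked_series_list")
}

#' Resample one masked series to S equal-duration bins
#'
#' The interval is split into `S` equal-duration bins; each bin takes the mean
#' of the raw updates falling in it (per attribute, ignoring `NA`s from
#' devices that did not update). Bins left empty are filled by linear
#' interpolation between the nearest non-empty bins, with nearest-value
#' extension at the edges. An attribute with no updates at all inside the
#' interval is filled with 0 (with a warning); if every attribute is empty the
#' series cannot be resampled and an error is raised.
#'
#' @param masked one element of [mask_by_intervals()] output.
#' @param S number of bins (default 8).
#' @return `S x Q` numeric matrix (attributes as named columns).
#' @export
resample_to_bins <- function(masked, S = 8) {
  stopifnot(S >= 1)
  v <- masked$values
  if (!nrow(v) || all(is.na(v))) {
    stop("masked series has zero updates in every attribute", call. = FALSE)
  }
  width <- masked$end - masked$start
  bin <- pmin(S, floor((masked$times - masked$start) / width * S) + 1L)
  Q <- ncol(v)
  sums <- matrix(0, S, Q, dimnames = list(NULL, colnames(v)))
  cnts <- matrix(0L, S, Q)
  obs <- !is.na(v)
  v0 <- ifelse(obs, v, 0)
  bs <- rowsum(v0, bin)
  bc <- rowsum(obs + 0L, bin)
  rows <- as.integer(rownames(bs))
  sums[rows, ] <- bs
  cnts[rows, ] <- bc
  out <- sums / cnts  # 0/0 -> NaN marks empty bins
  for (q in seq_len(Q)) {
    col <- out[, q]
    good <- which(is.finite(col))
    if (!length(good)) {
      warning("attribute ", colnames(v)[q],
              " has no updates in interval; filled with 0", call. = FALSE)
      out[, q] <- 0
    } else if (length(good) < S) {
      if (length(good) == 1L) {
        out[, q] <- col[good]
      } else {
        out[, q] <- stats::approx(good, col[good], xout = seq_len(S),
                                  rule = 2)$y
      }
    }
  }
  out
}

#' Assemble resampled compressions into a scaled feature tensor
#'
#' Stacks `N` matrices of identical shape `S x Q` into an `N x S x Q` array
#' and min-max scales each attribute to `[0, 1]` over the whole tensor
#' (scaling parameters are kept for reuse on new data). An attribute constant
#' everywhere has zero range and is mapped to 0 to keep the tensor finite.
#'
#' @param resampled list of `S x Q` matrices sharing dimensions and column
#'   names (from [resample_to_bins()]).
#' @param scale if `FALSE`, skip scaling (values kept raw, scaling table
#'   still computed).
#' @return object of class `feature_tensor`: list with `values`
#'   (`N x S x Q` array), `attribute_names`, `S`, and `scaling`
#'   (data.frame `attribute`, `min`, `max`).
#' @export
assemble_tensor <- function(resampled, scale = TRUE) {
  stopifnot(is.list(resampled), length(resampled) >= 1L)
  S <- nrow(resampled[[1L]])
  nm <- colnames(resampled[[1L]])
  Q <- length(nm)
  for (i in seq_along(resampled)) {
    m <- resampled[[i]]
    if (nrow(m) != S || ncol(m) != Q || !identical(colnames(m), nm)) {
      stop("compression ", i, " has inconsistent attributes: expected <",
           paste(utils::head(nm, 3), collapse = ","), ",...> got <",
           paste(utils::head(colnames(m), 3), collapse = ","), ",...>",
           call. = FALSE)
    }
  }
  N <- length(resampled)
  values <- array(NA_real_, dim = c(N, S, Q),
                  dimnames = list(NULL, NULL, nm))
  for (i in seq_len(N)) values[i, , ] <- resampled[[i]]
  mins <- apply(values, 3, min)
  maxs <- apply(values, 3, max)
  if (scale) {
    for (q in seq_len(Q)) {
      rng <- maxs[q] - mins[q]
      values[, , q] <- if (rng == 0) 0 else (values[, , q] - mins[q]) / rng
    }
  }
  structure(list(values = values, attribute_names = nm, S = S,
                 scaling = data.frame(attribute = nm, min = unname(mins),
                                      max = unname(maxs))),
            class = "feature_tensor")
}

#' @export
print.feature_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<feature_tensor> %d compressions x %d bins x %d attributes\n",
              d[1], d[2], d[3]))
  cat("  attributes:", paste(utils::head(x$attribute_names, 6),
                             collapse = ", "),
      if (length(x$attribute_names) > 6) "..." else "", "\n")
  invisible(x)
}

#' Build the feature tensor for one or more sessions
#'
#' Convenience wrapper running the full routine: per session, consolidate
#' sensor recordings, stack annotation intervals, mask, resample to `S` bins;
#' then assemble all compressions into one tensor scaled over the whole set.
#' Intervals whose masked series is empty across all attributes are dropped
#' (with a warning), keeping tensor rows aligned with the returned intervals.
#'
#' @param sessions an [mlt_session()] or list of them.
#' @param S bins per compression.
#' @param excluded_joints passed to [build_attribute_table()].
#' @param scale passed to [assemble_tensor()].
#' @return list with `tensor` ([assemble_tensor()] result) and `intervals`
#'   (the matching [build_interval_table()] rows).
#' @export
sessions_to_tensor <- function(sessions, S = 8,
                               excluded_joints = c("Ankle", "Hip", "Head"),
                               scale = TRUE) {
  if (inherits(sessions, "mlt_session")) sessions <- list(sessions)
  mats <- list()
  kept <- list()
  for (s in sessions) {
    at <- build_attribute_table(s, excluded_joints = excluded_joints)
    iv <- build_interval_table(s)
    if (!nrow(iv)) next
    masks <- mask_by_intervals(at, iv)
    for (i in seq_along(masks)) {
      if (isTRUE(attr(masks[[i]], "empty"))) next
      mats[[length(mats) + 1L]] <- resample_to_bins(masks[[i]], S = S)
      kept[[length(kept) + 1L]] <- iv[i, , drop = FALSE]
    }
  }
  if (!length(mats)) stop("no non-empty compression intervals", call. = FALSE)
  intervals <- as.data.frame(data.table::rbindlist(kept, fill = TRUE))
  list(tensor = assemble_tensor(mats, scale = scale), intervals = intervals)
}
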