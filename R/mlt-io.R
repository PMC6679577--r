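# MLT session archives: one directory (or zip) per recorded activity, holding a
# session.json manifest plus one JSON document per sensor/annotation recording.
# Sensor documents carry timestamped frames; annotation documents carry
# [start, end) intervals with per-compression measurements and/or labels.

#' Construct a sensor recording
#'
#' @param application_name name of the data-provider application
#'   (e.g. `"Kinect"`); also the file stem inside the archive.
#' @param frames data.frame with a numeric `timestamp` column (seconds,
#'   t0 = 0) and one numeric column per sensor attribute. Rows are sorted by
#'   timestamp (stable: input order kept on ties).
#' @param application_id identifier string.
#' @param time_offset seconds added to all timestamps downstream (manual
#'   alignment to the annotation stream); default 0.
#' @return object of class `sensor_recording`.
#' @export
sensor_recording <- function(application_name, frames,
                             application_id = application_name,
                             time_offset = 0) {
  stopifnot(is.character(application_name), nzchar(application_name))
  frames <- as.data.frame(frames)
  if (nrow(frames) > 0L) {
    if (!"timestamp" %in% names(frames)) {
      stop("frames must have a 'timestamp' column", call. = FALSE)
    }
    if (any(frames$timestamp < 0)) {
      stop("frame timestamps must be >= 0", call. = FALSE)
    }
    attrs <- setdiff(names(frames), "timestamp")
    if (any(!nzchar(attrs)) || anyDuplicated(attrs)) {
      stop("attribute names must be non-empty and unique", call. = FALSE)
    }
    frames <- frames[order(frames$timestamp), , drop = FALSE]
    rownames(frames) <- NULL
  }
  structure(
    list(application_id = application_id,
         application_name = application_name,
         frames = frames,
         time_offset = time_offset),
    class = "sensor_recording"
  )
}

#' Construct an annotation recording
#'
#' Each row of `intervals` is one chest compression: a half-open time interval
#' `[start, end)` carrying manikin measurements (`compDepth` mm,
#' `compMeanRate` compressions/min, `compRelease` mm) and/or class labels
#' (`classRate`, `classDepth`, `classRelease`, `armsLocked`, `bodyWeight`).
#'
#' @param application_name,application_id,time_offset as in
#'   [sensor_recording()].
#' @param intervals data.frame with numeric `start` and `end` columns
#'   (seconds) plus measurement/label columns.
#' @return object of class `annotation_recording`.
#' @export
annotation_recording <- function(application_name, intervals,
                                 application_id = application_name,
                                 time_offset = 0) {
  intervals <- as.data.frame(intervals)
  if (nrow(intervals) > 0L) {
    if (!all(c("start", "end") %in% names(intervals))) {
      stop("intervals must have 'start' and 'end' columns", call. = FALSE)
    }
    bad <- which(intervals$end <= intervals$start)
    if (length(bad)) {
      stop("interval(s) with end <= start at row(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    lab <- intersect(names(intervals),
                     c("classRate", "classDepth", "classRelease",
                       "armsLocked", "bodyWeight"))
    for (l in lab) {
      v <- intervals[[l]]
      if (any(!is.na(v) & !(v %in% 0:2))) {
        stop("label column ", sQuote(l), " must be in {0,1,2}", call. = FALSE)
      }
    }
    intervals <- intervals[order(intervals$start), , drop = FALSE]
    rownames(intervals) <- NULL
  }
  structure(
    list(application_id = application_id,
         application_name = application_name,
         intervals = intervals,
         time_offset = time_offset),
    class = "annotation_recording"
  )
}

#' Construct an MLT session
#'
#' A session bundles one or more time-synchronised recordings sharing the same
#' relative clock (t0 = 0) plus the absolute date-time at which the session was
#' recorded, used downstream to disambiguate sessions on a common axis.
#'
#' @param session_id identifier string.
#' @param sensor_recordings list of [sensor_recording()] objects.
#' @param annotation_recordings list of [annotation_recording()] objects.
#' @param recording_datetime `POSIXct` scalar.
#' @return object of class `mlt_session`.
#' @export
mlt_session <- function(session_id,
                        sensor_recordings = list(),
                        annotation_recordings = list(),
                        recording_datetime = as.POSIXct("2019-01-01 00:00:00",
                                                        tz = "UTC")) {
  stopifnot(inherits(recording_datetime, "POSIXct"))
  for (r in sensor_recordings) stopifnot(inherits(r, "sensor_recording"))
  for (r in annotation_recordings) stopifnot(inherits(r, "annotation_recording"))
  names(sensor_recordings) <-
    vapply(sensor_recordings, `[[`, "", "application_name")
  names(annotation_recordings) <-
    vapply(annotation_recordings, `[[`, "", "application_name")
  structure(
    list(session_id = session_id,
         recording_datetime = recording_datetime,
         sensor_recordings = sensor_recordings,
         annotation_recordings = annotation_recordings),
    class = "mlt_session"
  )
}

#' @export
print.mlt_session <- function(x, ...) {
  cat("<mlt_session>", x$session_id, "recorded",
      format(x$recording_datetime, usetz = TRUE), "\n")
  for (r in x$sensor_recordings) {
    n <- nrow(r$frames)
    span <- if (n) sprintf("%.3f-%.3f s", min(r$frames$timestamp),
                           max(r$frames$timestamp)) else "empty"
    cat(sprintf("  sensor     %-12s %5d frames  %2d attrs  %s\n",
                r$application_name, n, ncol(r$frames) - (n > 0), span))
  }
  for (r in x$annotation_recordings) {
    cat(sprintf("  annotation %-12s %5d intervals\n",
                r$application_name, nrow(r$intervals)))
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# serialisation

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, dataframe = "rows", digits = NA,
                       auto_unbox = TRUE, pretty = FALSE, na = "null")
}

#' Write an MLT session archive
#'
#' Emits a directory containing `session.json` (manifest: session id,
#' recording date-time, list of recordings) and one
#' `<applicationName>.json` per recording. Sensor frames are written with a
#' `frameStamp` string in the full `"HH:MM:SS.fffffff"` dialect; annotation
#' frames carry `start`/`end` strings instead of a single stamp. Output is
#' byte-stable for a given session (fixed serialisation options).
#'
#' @param session an [mlt_session()].
#' @param path directory to create (must not collide with an existing file).
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "mlt_session"))
  if (file.exists(path) && !dir.exists(path)) {
    stop("cannot write session: ", path, " exists and is not a directory",
         call. = FALSE)
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("could not create directory ", path, call. = FALSE)

  entry <- function(r, type) {
    list(applicationId = r$application_id,
         applicationName = r$application_name,
         file = paste0(r$application_name, ".json"),
         type = type,
         timeOffset = r$time_offset)
  }
  manifest <- list(
    sessionId = session$session_id,
    recordingDateTime = format(session$recording_datetime,
                               "%Y-%m-%dT%H:%M:%OS6", tz = "UTC"),
    recordings = c(lapply(session$sensor_recordings, entry, type = "sensor"),
                   lapply(session$annotation_recordings, entry,
                          type = "annotation"))
  )
  names(manifest$recordings) <- NULL
  .write_json(manifest, file.path(path, "session.json"))

  for (r in session$sensor_recordings) {
    fr <- r$frames
    if (nrow(fr)) {
      out <- cbind(data.frame(frameStamp = format_mlt_timestamp(fr$timestamp),
                              stringsAsFactors = FALSE),
                   fr[setdiff(names(fr), "timestamp")])
    } else {
      out <- list()
    }
    .write_json(list(applicationId = r$application_id,
                     applicationName = r$application_name,
                     frames = out),
                file.path(path, paste0(r$application_name, ".json")))
  }
  for (r in session$annotation_recordings) {
    iv <- r$intervals
    if (nrow(iv)) {
      out <- cbind(data.frame(start = format_mlt_timestamp(iv$start),
                              end = format_mlt_timestamp(iv$end),
                              stringsAsFactors = FALSE),
                   iv[setdiff(names(iv), c("start", "end"))])
    } else {
      out <- list()
    }
    .write_json(list(applicationId = r$application_id,
                     applicationName = r$application_name,
                     frames = out),
                file.path(path, paste0(r$application_name, ".json")))
  }
  invisible(path)
}

#' Read an MLT session archive
#'
#' Accepts a directory or a `.zip` file. Recordings are discovered through the
#' `session.json` manifest when present, otherwise every `*.json` document in
#' the folder is classified by content: frames with `start`/`end` fields are
#' annotation intervals, frames with a single `frameStamp` are sensor frames.
#' Video files (`.mp4`) are ignored.
#'
#' @param path directory or zip archive.
#' @return an [mlt_session()].
#' @export
read_session <- function(path) {
  if (!file.exists(path)) stop("no such session: ", path, call. = FALSE)
  if (!dir.exists(path)) {
    if (!grepl("\\.zip$", path, ignore.case = TRUE)) {
      stop("session path must be a directory or .zip archive: ", path,
           call. = FALSE)
    }
    ex <- file.path(tempfile("mltzip"), "x")
    dir.create(ex, recursive = TRUE)
    utils::unzip(path, exdir = ex)
    # tolerate archives that wrap everything in a single top-level folder
    inner <- list.dirs(ex, recursive = FALSE)
    if (!length(list.files(ex, pattern = "\\.json$")) && length(inner) == 1L) {
      ex <- inner
    }
    path <- ex
  }

  manifest_file <- file.path(path, "session.json")
  session_id <- basename(path)
  datetime <- as.POSIXct("2019-01-01 00:00:00", tz = "UTC")
  offsets <- list()
  if (file.exists(manifest_file)) {
    man <- tryCatch(
      jsonlite::read_json(manifest_file, simplifyVector = FALSE),
      error = function(e) stop("unparseable JSON in ", manifest_file, ": ",
                               conditionMessage(e), call. = FALSE))
    if (!is.null(man$sessionId)) session_id <- man$sessionId
    if (!is.null(man$recordingDateTime)) {
      datetime <- as.POSIXct(man$recordingDateTime,
                             format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
    }
    for (rec in man$recordings %||% list()) {
      if (!is.null(rec$file) && !is.null(rec$timeOffset)) {
        offsets[[rec$file]] <- rec$timeOffset
      }
    }
  }

  files <- setdiff(list.files(path, pattern = "\\.json$"), "session.json")
  sensors <- list()
  annots <- list()
  for (f in files) {
    doc <- tryCatch(
      jsonlite::fromJSON(file.path(path, f), simplifyVector = TRUE,
                         simplifyDataFrame = TRUE),
      error = function(e) stop("unparseable JSON in ", f, ": ",
                               conditionMessage(e), call. = FALSE))
    app_name <- doc$applicationName %||% sub("\\.json$", "", f)
    app_id <- doc$applicationId %||% app_name
    off <- offsets[[f]] %||% 0
    fr <- doc$frames
    if (is.null(fr) || length(fr) == 0L) {
      sensors[[length(sensors) + 1L]] <-
        sensor_recording(app_name, data.frame(timestamp = numeric(0)),
                         app_id, off)
      next
    }
    fr <- as.data.frame(fr)
    if (all(c("start", "end") %in% names(fr))) {
      fr$start <- parse_mlt_timestamp(fr$start)
      fr$end <- parse_mlt_timestamp(fr$end)
      annots[[length(annots) + 1L]] <-
        annotation_recording(app_name, fr, app_id, off)
    } else if ("frameStamp" %in% names(fr)) {
      bad <- which(is.na(fr$frameStamp))
      if (length(bad)) {
        stop("format error in ", f, ": frame(s) missing timestamp at index ",
             paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
      }
      ts <- tryCatch(parse_mlt_timestamp(fr$frameStamp), error = function(e) {
        stop("in ", f, ": ", conditionMessage(e), call. = FALSE)
      })
      fr$frameStamp <- NULL
      fr <- cbind(data.frame(timestamp = ts), fr)
      sensors[[length(sensors) + 1L]] <-
        sensor_recording(app_name, fr, app_id, off)
    } else {
      stop("format error in ", f,
           ": frames lack both 'frameStamp' and 'start'/'end' fields",
           call. = FALSE)
    }
  }
  mlt_session(session_id, sensors, annots, datetime)
}

# ---------------------------------------------------------------------------
# time alignment

#' Shift a recording in time
#'
#' Returns a copy of the recording with every timestamp (sensor frames) or
#' `start`/`end` pair (annotation intervals) shifted by `offset_seconds`;
#' ordering is preserved and the input is left unmodified. Used to align the
#' manikin annotation stream, whose clock starts independently, onto the
#' sensor clock.
#'
#' @param recording a `sensor_recording`, `annotation_recording`, or
#'   `mlt_session` (all recordings shifted).
#' @param offset_seconds signed shift in seconds.
#' @param allow_negative if `FALSE`, a shift that produces a negative time
#'   raises a validation error.
#' @return shifted object of the same class.
#' @export
apply_offset <- function(recording, offset_seconds, allow_negative = TRUE) {
  UseMethod("apply_offset")
}

#' @export
apply_offset.sensor_recording <- function(recording, offset_seconds,
                                          allow_negative = TRUE) {
  if (nrow(recording$frames)) {
    ts <- recording$frames$timestamp + offset_seconds
    if (!allow_negative && any(ts < 0)) {
      stop("offset produces negative timestamps", call. = FALSE)
    }
    recording$frames$timestamp <- ts
  }
  recording
}

#' @export
apply_offset.annotation_recording <- function(recording, offset_seconds,
                                              allow_negative = TRUE) {
  if (nrow(recording$intervals)) {
    s <- recording$intervals$start + offset_seconds
    if (!allow_negative && any(s < 0)) {
      stop("offset produces negative interval starts", call. = FALSE)
    }
    recording$intervals$start <- s
    recording$intervals$end <- recording$intervals$end + offset_seconds
  }
  recording
}

#' @export
apply_offset.mlt_session <- function(recording, offset_seconds,
                                     allow_negative = TRUE) {
  recording$sensor_recordings <-
    lapply(recording$sensor_recordings, apply_offset, offset_seconds,
           allow_negative)
  recording$annotation_recordings <-
    lapply(recording$annotation_recordings, apply_offset, offset_seconds,
           allow_negative)
  recording
}

`%||%` <- function(a, b) if (is.null(a)) b else a
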