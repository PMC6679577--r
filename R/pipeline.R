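# End-to-end orchestration: simulate (or load) -> align -> label ->
# preprocess -> train -> evaluate, reproducibly from one config.

#' Configuration for a full pipeline run
#'
#' Exactly one of `cohort` (simulation parameter sets; "participants" are
#' parameter settings) or `session_paths` (MLT archives on disk) supplies the
#' input sessions.
#'
#' @param cohort list of [simulation_params()].
#' @param session_paths character vector of MLT archive paths.
#' @param thresholds a [guideline_thresholds()].
#' @param bins bins per compression (S).
#' @param excluded_joints passed to preprocessing.
#' @param targets label columns to train classifiers for.
#' @param hidden_units,test_fraction,batch_size forwarded to
#'   [classifier_config()].
#' @param epochs_ternary,epochs_binary epoch budgets by target arity.
#' @param seed global seed; propagated to every stochastic stage (per-session
#'   simulation seeds and per-target split/init seeds are derived from it).
#' @param output_dir if non-`NULL`, artifacts (sessions, labeled intervals,
#'   reports, manifest) are written there.
#' @return object of class `run_config`.
#' @export
run_config <- function(cohort = NULL, session_paths = NULL,
                       thresholds = guideline_thresholds(), bins = 8,
                       excluded_joints = c("Ankle", "Hip", "Head"),
                       targets = c("classRate", "classDepth", "classRelease",
                                   "armsLocked", "bodyWeight"),
                       hidden_units = 128, test_fraction = 0.33,
                       batch_size = 32,
                       epochs_ternary = 30, epochs_binary = 100,
                       seed = 1, output_dir = NULL) {
  if (is.null(cohort) == is.null(session_paths)) {
    stop("supply exactly one of 'cohort' or 'session_paths'", call. = FALSE)
  }
  if (!is.null(session_paths)) {
    missing <- session_paths[!file.exists(session_paths)]
    if (length(missing)) {
      stop("session path(s) not found: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
  }
  if (!is.null(cohort)) {
    for (p in cohort) stopifnot(inherits(p, "simulation_params"))
  }
  structure(as.list(environment())[
    c("cohort", "session_paths", "thresholds", "bins", "excluded_joints",
      "targets", "hidden_units", "test_fraction", "batch_size",
      "epochs_ternary", "epochs_binary", "seed", "output_dir")],
    class = "run_config")
}

.ternary_targets <- c("classRate", "classDepth")

#' Run the full mistake-detection pipeline
#'
#' Simulates or reads the sessions, labels every compression against the
#' guideline thresholds, builds the scaled feature tensor, then for each
#' target trains an LSTM classifier (validation = the held-out test split,
#' whose metrics are monitored per epoch) and evaluates it. Any stage failure
#' aborts with the stage name and the offending session.
#'
#' @param config a [run_config()].
#' @param quiet suppress per-stage progress messages.
#' @return object of class `summary_report`: `annotation_summary`
#'   (per-indicator mean/std/min/max), `class_distribution` (per-target
#'   counts), `eval_reports` (named list of [evaluate_classifier()] reports),
#'   `histories`, `n_compressions`, and `manifest` (settings + seeds +
#'   version, sufficient to recompute every number in the report).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, who, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed for ", who, ": ",
           conditionMessage(e), call. = FALSE)
    })
  }

  # --- acquire sessions ----------------------------------------------------
  if (!is.null(config$cohort)) {
    sessions <- vector("list", length(config$cohort))
    for (i in seq_along(config$cohort)) {
      p <- config$cohort[[i]]
      if (is.null(p$seed)) p$seed <- (config$seed * 131L + i) %% 2147483647L
      sessions[[i]] <- stage("simulate", paste0("cohort entry ", i), {
        sim <- simulate_session(p, session_id = sprintf("sim-%03d", i),
                                recording_datetime =
                                  as.POSIXct("2019-01-01 00:00:00",
                                             tz = "UTC") + (i - 1) * 600)
        sim$session
      })
    }
    say("simulated ", length(sessions), " session(s)")
  } else {
    sessions <- lapply(config$session_paths, function(pth) {
      stage("read", pth, read_session(pth))
    })
    say("read ", length(sessions), " session(s)")
  }

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    for (s in sessions) {
      stage("write", s$session_id,
            write_session(s, file.path(config$output_dir, s$session_id)))
    }
  }

  # --- label ---------------------------------------------------------------
  for (i in seq_along(sessions)) {
    s <- sessions[[i]]
    s$annotation_recordings <- lapply(
      s$annotation_recordings,
      function(r) stage("label", s$session_id,
                        label_compressions(r, config$thresholds)))
    sessions[[i]] <- s
  }

  # --- preprocess ----------------------------------------------------------
  prep <- stage("preprocess", "cohort",
                sessions_to_tensor(sessions, S = config$bins,
                                   excluded_joints = config$excluded_joints))
  intervals <- prep$intervals
  N <- nrow(intervals)
  say("tensor: ", N, " x ", prep$tensor$S, " x ",
      length(prep$tensor$attribute_names))

  ann_summary <- summarize_annotations(intervals)
  targets <- intersect(config$targets, names(intervals))
  class_dist <- lapply(targets, function(tg) table(intervals[[tg]]))
  names(class_dist) <- targets

  # --- train / evaluate ----------------------------------------------------
  reports <- list(); histories <- list(); model_seeds <- list()
  for (ti in seq_along(targets)) {
    tg <- targets[ti]
    y <- as.integer(intervals[[tg]])
    k <- if (tg %in% .ternary_targets) 3L else 2L
    if (length(unique(y)) < 2L) {
      say("target ", tg, ": single class observed, skipped")
      next
    }
    sd_t <- (config$seed * 977L + ti) %% 2147483647L
    cfg <- classifier_config(
      n_classes = k, hidden_units = config$hidden_units,
      epochs = if (k == 3L) config$epochs_ternary else config$epochs_binary,
      batch_size = config$batch_size,
      test_fraction = config$test_fraction, seed = sd_t)
    split <- split_train_test(prep$tensor, y, cfg)
    model <- stage("train", tg,
                   train_classifier(split$train$x, split$train$y, cfg,
                                    validation = split$test))
    reports[[tg]] <- stage("evaluate", tg,
                           evaluate_classifier(model, split$test$x,
                                               split$test$y))
    histories[[tg]] <- model$history
    model_seeds[[tg]] <- sd_t
    say(sprintf("target %-12s accuracy %.4f loss %.4f", tg,
                reports[[tg]]$accuracy, reports[[tg]]$loss))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("cprtutor")),
    seed = config$seed,
    model_seeds = model_seeds,
    bins = config$bins,
    excluded_joints = config$excluded_joints,
    thresholds = unclass(config$thresholds),
    hidden_units = config$hidden_units,
    batch_size = config$batch_size,
    test_fraction = config$test_fraction,
    epochs = list(ternary = config$epochs_ternary,
                  binary = config$epochs_binary),
    n_sessions = length(sessions),
    n_compressions = N,
    attributes = prep$tensor$attribute_names
  )

  report <- structure(
    list(annotation_summary = ann_summary,
         class_distribution = class_dist,
         eval_reports = reports,
         histories = histories,
         intervals = intervals,
         tensor = prep$tensor,
         n_compressions = N,
         manifest = manifest),
    class = "summary_report")

  if (!is.null(config$output_dir)) {
    utils::write.csv(intervals[setdiff(names(intervals), "abs_start")],
                     file.path(config$output_dir, "labeled_intervals.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest,
                         file.path(config$output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    ev <- lapply(reports, function(r) {
      list(accuracy = r$accuracy, loss = r$loss, roc_auc = r$roc_auc,
           overfit_epoch = r$overfit_epoch, n_test = r$n_test,
           confusion = r$confusion)
    })
    jsonlite::write_json(ev, file.path(config$output_dir, "eval_reports.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         matrix = "rowmajor")
  }
  report
}

#' Summary statistics of per-compression annotation measurements
#'
#' @param intervals an interval table or data.frame with measurement columns
#'   (`compDepth`, `compMeanRate`, `compRelease`, `duration`; any subset).
#' @return data.frame: one row per indicator with `mean`, `std`, `min`,
#'   `max`.
#' @export
summarize_annotations <- function(intervals) {
  intervals <- as.data.frame(intervals)
  if (!nrow(intervals)) stop("no intervals to summarise", call. = FALSE)
  cols <- intersect(c("compDepth", "compMeanRate", "compRelease", "duration"),
                    names(intervals))
  out <- data.frame(indicator = cols,
                    mean = NA_real_, std = NA_real_,
                    min = NA_real_, max = NA_real_)
  for (i in seq_along(cols)) {
    v <- intervals[[cols[i]]]
    out$mean[i] <- mean(v)
    out$std[i] <- if (length(v) > 1L) stats::sd(v) else 0
    out$min[i] <- min(v)
    out$max[i] <- max(v)
  }
  out
}

#' @export
print.summary_report <- function(x, ...) {
  cat("<summary_report>", x$n_compressions, "compressions\n")
  cat("\nannotation summary:\n")
  print(x$annotation_summary, row.names = FALSE)
  cat("\nclass distributions:\n")
  for (tg in names(x$class_distribution)) {
    d <- x$class_distribution[[tg]]
    cat(sprintf("  %-12s %s\n", tg,
                paste(names(d), as.integer(d), sep = ":", collapse = "  ")))
  }
  if (length(x$eval_reports)) {
    cat("\nclassifier performance:\n")
    for (tg in names(x$eval_reports)) {
      r <- x$eval_reports[[tg]]
      cat(sprintf("  %-12s accuracy %.4f  loss %.4f  ROC-AUC %s\n", tg,
                  r$accuracy, r$loss,
                  if (is.na(r$roc_auc)) "n.a." else sprintf("%.4f", r$roc_auc)))
    }
  }
  invisible(x)
}
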