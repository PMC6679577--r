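# Recurrent classifier per performance indicator: LSTM hidden layer (default
# 128 units) + dense softmax output (2 or 3 classes), sparse categorical
# cross-entropy, random-shuffle 66/33 train/test split.

#' Configuration of a compression-quality classifier
#'
#' @param n_classes 2 (binary indicators: release, arms, body weight) or
#'   3 (ternary: rate, depth).
#' @param hidden_units LSTM hidden layer width.
#' @param epochs training iterations over the full training set (convention:
#'   30 for ternary targets, 100 for binary ones).
#' @param batch_size minibatch size (unstated upstream; 32 is the standard
#'   default and is recorded in run metadata).
#' @param learning_rate Adam step size.
#' @param test_fraction held-out fraction; test size is
#'   `round(test_fraction * N)`.
#' @param seed RNG seed for shuffling and weight initialisation.
#' @return object of class `classifier_config`.
#' @export
classifier_config <- function(n_classes, hidden_units = 128,
                              epochs = if (n_classes == 3) 30 else 100,
                              batch_size = 32, learning_rate = 1e-3,
                              test_fraction = 0.33, seed = NULL) {
  stopifnot(n_classes %in% c(2L, 3L))
  stopifnot(test_fraction > 0, test_fraction < 1, epochs >= 1,
            hidden_units >= 1, batch_size >= 1, learning_rate > 0)
  structure(list(n_classes = as.integer(n_classes),
                 hidden_units = as.integer(hidden_units),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 test_fraction = test_fraction,
                 seed = seed),
            class = "classifier_config")
}

.tensor_values <- function(x) {
  if (inherits(x, "feature_tensor")) x$values else x
}

#' Split a tensor and its labels into train and test partitions
#'
#' Random shuffling (seeded, reproducible); the partitions are disjoint and
#' exhaustive with test size `round(test_fraction * N)`. No stratification: a
#' class missing from the training partition only raises a warning.
#'
#' @param x `feature_tensor` or `N x S x Q` array.
#' @param y integer labels (0-based), length `N`.
#' @param config a [classifier_config()] (supplies `test_fraction` and
#'   `seed`), or `NULL` to use the explicit arguments.
#' @param test_fraction,seed used when `config` is `NULL`.
#' @return list with `train` and `test`, each holding `x` (array), `y`, and
#'   the original `idx`.
#' @export
split_train_test <- function(x, y, config = NULL, test_fraction = 0.33,
                             seed = NULL) {
  if (!is.null(config)) {
    test_fraction <- config$test_fraction
    seed <- config$seed
  }
  xv <- .tensor_values(x)
  N <- dim(xv)[1]
  stopifnot(N == length(y))
  if (!is.null(seed)) set.seed(seed)
  n_test <- round(test_fraction * N)
  if (n_test < 1 || n_test >= N) stop("degenerate split", call. = FALSE)
  perm <- sample.int(N)
  test_idx <- sort(perm[seq_len(n_test)])
  train_idx <- sort(perm[-seq_len(n_test)])
  if (length(setdiff(unique(y), unique(y[train_idx])))) {
    warning("class absent from the training partition", call. = FALSE)
  }
  list(train = list(x = xv[train_idx, , , drop = FALSE], y = y[train_idx],
                    idx = train_idx),
       test = list(x = xv[test_idx, , , drop = FALSE], y = y[test_idx],
                   idx = test_idx))
}

#' Train an LSTM compression-quality classifier
#'
#' Minimises sparse categorical cross-entropy with Adam over minibatches; no
#' early stopping — the full epoch budget is run and the overfitting point is
#' read retrospectively with [detect_overfit_epoch()]. Training-set loss and
#' accuracy are the running averages over the epoch's minibatches (as training
#' frameworks report them); validation metrics are computed on `validation`
#' after each epoch when supplied, else recorded as `NA`.
#'
#' @param x training inputs (`feature_tensor` or array), scaled to `[0, 1]`.
#' @param y integer labels in `0:(n_classes - 1)`.
#' @param config a [classifier_config()].
#' @param validation optional list with `x` and `y` monitored each epoch.
#' @return object of class `cpr_classifier`: the fitted parameters, the
#'   config, and `history` (data.frame: `epoch`, `loss`, `accuracy`,
#'   `val_loss`, `val_accuracy`).
#' @export
train_classifier <- function(x, y, config, validation = NULL) {
  stopifnot(inherits(config, "classifier_config"))
  X <- .tensor_values(x)
  y <- as.integer(y)
  N <- dim(X)[1]
  stopifnot(N == length(y))
  if (any(y < 0L | y >= config$n_classes)) {
    stop("labels must lie in 0:(n_classes-1); got values ",
         paste(sort(unique(y)), collapse = ","), call. = FALSE)
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  par <- lstm_init(Q = dim(X)[3], H = config$hidden_units,
                   K = config$n_classes)
  st <- adam_state(par)
  hist <- data.frame(epoch = seq_len(config$epochs), loss = NA_real_,
                     accuracy = NA_real_, val_loss = NA_real_,
                     val_accuracy = NA_real_)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(N)
    losses <- c(); accs <- c(); wts <- c()
    for (start in seq(1L, N, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, N)]
      Xb <- X[idx, , , drop = FALSE]
      yb <- y[idx]
      fwd <- lstm_forward(par, Xb, keep_cache = TRUE)
      la <- lstm_loss_acc(fwd$probs, yb)
      grads <- lstm_backward(par, Xb, yb, fwd)
      upd <- adam_update(par, grads, st, lr = config$learning_rate)
      par <- upd$par; st <- upd$state
      losses <- c(losses, la$loss); accs <- c(accs, la$acc)
      wts <- c(wts, length(idx))
    }
    hist$loss[ep] <- sum(losses * wts) / sum(wts)
    hist$accuracy[ep] <- sum(accs * wts) / sum(wts)
    if (!is.null(validation)) {
      vf <- lstm_forward(par, .tensor_values(validation$x))
      vla <- lstm_loss_acc(vf$probs, as.integer(validation$y))
      hist$val_loss[ep] <- vla$loss
      hist$val_accuracy[ep] <- vla$acc
    }
  }
  structure(list(parameters = par, config = config, history = hist),
            class = "cpr_classifier")
}

#' Class-probability predictions
#'
#' @param object a fitted [train_classifier()] model.
#' @param x inputs (`feature_tensor` or array).
#' @param ... unused.
#' @return `N x n_classes` matrix of softmax probabilities.
#' @export
predict.cpr_classifier <- function(object, x, ...) {
  lstm_forward(object$parameters, .tensor_values(x))$probs
}

#' Locate the overfitting point in a training history
#'
#' The epoch at which validation loss stops improving while training loss
#' keeps decreasing, operationalised as the 1-based epoch of minimum
#' validation loss (earliest epoch on ties). Invariant to appending further
#' epochs after the minimum.
#'
#' @param history data.frame with a `val_loss` column (as produced by
#'   [train_classifier()]), or a numeric vector of validation losses.
#' @return integer epoch index.
#' @export
detect_overfit_epoch <- function(history) {
  v <- if (is.data.frame(history)) history$val_loss else as.numeric(history)
  if (!length(v)) stop("empty history", call. = FALSE)
  which.min(v)  # earliest on ties
}

#' Area under the ROC curve from scores
#'
#' Rank-based (Mann-Whitney) AUC with midrank tie handling; a constant scorer
#' therefore yields exactly 0.5. Returns `NA` when only one class is present.
#'
#' @param scores numeric scores for the positive class.
#' @param labels binary labels (0/1).
#' @return AUC in `[0, 1]`, or `NA`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a classifier on a test partition
#'
#' @param model a fitted [train_classifier()] model.
#' @param x,y test inputs and 0-based labels.
#' @return object of class `eval_report`: `accuracy` (fraction of argmax
#'   predictions equal to the labels), `loss` (mean sparse categorical
#'   cross-entropy), `roc_auc` (class-1 scores, binary targets only, `NA`
#'   otherwise or when the test set is single-class), `confusion` (matrix,
#'   rows = actual, columns = predicted), `n_test`, and `overfit_epoch` (from
#'   the model's validation history, `NA` if none was recorded).
#' @export
evaluate_classifier <- function(model, x, y) {
  stopifnot(inherits(model, "cpr_classifier"))
  y <- as.integer(y)
  if (!length(y)) stop("test set is empty", call. = FALSE)
  probs <- predict(model, x)
  la <- lstm_loss_acc(probs, y)
  K <- model$config$n_classes
  pred <- max.col(probs, ties.method = "first") - 1L
  confusion <- table(factor(y, levels = 0:(K - 1)),
                     factor(pred, levels = 0:(K - 1)))
  confusion <- unclass(confusion)
  names(dimnames(confusion)) <- c("actual", "predicted")
  auc <- if (K == 2L) roc_auc(probs[, 2L], y) else NA_real_
  ofe <- if (all(is.na(model$history$val_loss))) NA_integer_ else
    detect_overfit_epoch(model$history)
  structure(list(accuracy = la$acc, loss = la$loss, roc_auc = auc,
                 confusion = confusion, n_test = length(y),
                 overfit_epoch = ofe),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> accuracy %.4f  loss %.4f  ROC-AUC %s  (n = %d)\n",
              x$accuracy, x$loss,
              if (is.na(x$roc_auc)) "n.a." else sprintf("%.4f", x$roc_auc),
              x$n_test))
  if (!is.na(x$overfit_epoch)) {
    cat("  overfitting point: epoch", x$overfit_epoch, "\n")
  }
  print(x$confusion)
  invisible(x)
}
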