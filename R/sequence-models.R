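#' Sequence model specification
#'
#' A single recurrent cell (GRU or LSTM) followed by a fully connected
#' sigmoid head for binary classification. Training defaults follow the
#' documented protocol: 100 epochs, batch size 256, Adam at learning rate
#' 1e-3; the hidden width (64) and binary cross-entropy loss are package
#' defaults, logged with every run.
#'
#' @param cell `"gru"` or `"lstm"`.
#' @param hidden_dim recurrent state width (default 64).
#' @param epochs training epochs (default 100).
#' @param batch_size mini-batch size (default 256).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param frame_stride temporal subsampling of the window's frame sequence
#'   before the recurrent cell (1 = every frame, the documented protocol;
#'   larger values trade sequence resolution for compute and are recorded
#'   on every report).
#' @param seed integer seed.
#' @return list of class `sequence_model_spec`.
#' @export
sequence_model_spec <- function(cell = c("gru", "lstm"), hidden_dim = 64L,
                                epochs = 100L, batch_size = 256L,
                                learning_rate = 1e-3, frame_stride = 1L,
                                seed = 1L) {
  cell <- match.arg(cell)
  structure(list(cell = cell, hidden_dim = as.integer(hidden_dim),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 frame_stride = as.integer(frame_stride),
                 seed = as.integer(seed)),
            class = "sequence_model_spec")
}

# per-feature standardization statistics from the training tensor
.seq_standardize <- function(tensor, mu = NULL, sdv = NULL) {
  d <- dim(tensor)
  flat <- matrix(tensor, nrow = d[1L])
  if (is.null(mu)) {
    mu <- rowMeans(flat)
    sdv <- apply(flat, 1L, stats::sd)
    sdv[sdv == 0 | !is.finite(sdv)] <- 1
  }
  array((flat - mu) / sdv, d)
}

#' Train and evaluate a sequence classifier over pose windows
#'
#' Stratified random split at window level (the documented protocol; note
#' that with a 1-second stride adjacent windows overlap, so a window-level
#' split shares frames between partitions — `split_mode = "episode"`
#' instead assigns whole ground-truth episodes, giving a leakage-free
#' evaluation, and is flagged in the report). Features are standardized
#' with training-split statistics; training minimizes binary cross-entropy
#' on the sigmoid output of the final hidden state. Deterministic under
#' the seed (single-threaded).
#'
#' @param windows a `pose_windows` object from [build_windows()].
#' @param spec a [sequence_model_spec()].
#' @param split train fraction (default 0.7).
#' @param split_mode `"window"` (default, documented protocol) or
#'   `"episode"`.
#' @param threshold decision threshold on the sigmoid output (default 0.5).
#' @return list of class `sequence_model`: `spec`, `fit`, `mu`, `sd`,
#'   `feature_names`, `report` (a [metrics_report()] with `split_mode`),
#'   `train_loss` (per-epoch).
#' @export
train_sequence_model <- function(windows, spec, split = 0.7,
                                 split_mode = c("window", "episode"),
                                 threshold = 0.5) {
  split_mode <- match.arg(split_mode)
  stopifnot(inherits(windows, "pose_windows"))
  n <- length(windows$labels)
  if (n < 2L) stop("protocol error: need at least 2 windows")
  y <- as.numeric(windows$labels == "agitation")
  if (length(unique(y)) < 2L)
    stop("protocol error: both classes must be present")
  sp <- if (split_mode == "window") {
    stratified_split(windows$labels, split, spec$seed)
  } else {
    # group windows by runs of identical label over time; split whole
    # runs, stratified by run label so both classes reach the test side
    runs <- cumsum(c(1L, diff(as.integer(as.factor(windows$labels))) != 0))
    run_lab <- tapply(windows$labels, runs, `[`, 1L)
    tr_runs <- with_seed(spec$seed, {
      unlist(lapply(unique(run_lab), function(cl) {
        rs <- as.integer(names(run_lab)[run_lab == cl])
        k <- max(1L, round(length(rs) * split))
        if (k >= length(rs)) k <- length(rs) - 1L
        if (k < 1L) integer() else sample(rs, k)
      }))
    })
    list(train = which(runs %in% tr_runs),
         test = which(!runs %in% tr_runs))
  }
  if (!length(sp$test) || length(unique(y[sp$test])) < 2L)
    stop("protocol error: test split lacks both classes")
  tidx <- seq(1L, dim(windows$tensor)[2L], by = max(1L, spec$frame_stride))
  Xtr <- windows$tensor[, tidx, sp$train, drop = FALSE]
  Xte <- windows$tensor[, tidx, sp$test, drop = FALSE]
  d <- dim(Xtr)
  flat <- matrix(Xtr, nrow = d[1L])
  mu <- rowMeans(flat)
  sdv <- apply(flat, 1L, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  Xtr <- .seq_standardize(Xtr, mu, sdv)
  Xte <- .seq_standardize(Xte, mu, sdv)
  fit <- with_seed(spec$seed,
                   cpp_train_rnn(Xtr, y[sp$train],
                                 ifelse(spec$cell == "gru", 0L, 1L),
                                 spec$hidden_dim, spec$epochs,
                                 spec$batch_size, spec$learning_rate))
  sc <- as.numeric(cpp_predict_rnn(fit, Xte))
  rep <- metrics_report(y[sp$test], sc, threshold = threshold,
                        algo = spec$cell)
  rep$split_mode <- split_mode
  structure(list(spec = spec, fit = fit, mu = mu, sd = sdv,
                 feature_names = windows$feature_names, report = rep,
                 train_loss = as.numeric(fit$epoch_loss),
                 split = sp),
            class = "sequence_model")
}

#' Predict with a trained sequence model
#' @param object a `sequence_model`.
#' @param windows a `pose_windows` object with the same feature manifest.
#' @param ... unused.
#' @return numeric agitation probabilities, one per window.
#' @export
predict.sequence_model <- function(object, windows, ...) {
  if (!identical(windows$feature_names, object$feature_names))
    stop("contract error: feature manifest mismatch")
  tidx <- seq(1L, dim(windows$tensor)[2L],
              by = max(1L, object$spec$frame_stride))
  X <- .seq_standardize(windows$tensor[, tidx, , drop = FALSE],
                        object$mu, object$sd)
  as.numeric(cpp_predict_rnn(object$fit, X))
}

#' Per-window inference latency
#'
#' Median and interquartile range of wall-clock single-window inference
#' time over repeated runs. Descriptive metadata only — latency is
#' hardware-dependent and never an acceptance quantity.
#'
#' @param model a `sequence_model`.
#' @param windows a `pose_windows` object.
#' @param repetitions number of timed repetitions (default 10).
#' @return list `median_s`, `iqr_s`, `repetitions`.
#' @export
evaluate_latency <- function(model, windows, repetitions = 10L) {
  if (repetitions < 1L) stop("protocol error: repetitions must be >= 1")
  tidx <- seq(1L, dim(windows$tensor)[2L],
              by = max(1L, model$spec$frame_stride))
  X <- .seq_standardize(windows$tensor[, tidx, 1L, drop = FALSE],
                        model$mu, model$sd)
  one <- X
  times <- vapply(seq_len(repetitions), function(i) {
    t0 <- proc.time()[["elapsed"]]
    cpp_predict_rnn(model$fit, one)
    proc.time()[["elapsed"]] - t0
  }, 0)
  list(median_s = stats::median(times), iqr_s = stats::IQR(times),
       repetitions = repetitions)
}

#' Compare sequence models across feature sets
#'
#' Trains every cell on the full manifest and on a correlation-reduced
#' manifest with the same data and split seed, and tabulates accuracy,
#' AUC, F1, recall and latency in a single comparison grid.
#'
#' @param windows_full `pose_windows` built on the full manifest.
#' @param windows_reduced `pose_windows` built on the reduced manifest
#'   (same stream, same windows).
#' @param specs list of [sequence_model_spec()] (default GRU and LSTM with
#'   shared seed).
#' @param split train fraction.
#' @param latency_reps repetitions for [evaluate_latency()].
#' @return data.frame: one row per cell x feature set, plus the fitted
#'   models in `attr(, "models")`.
#' @export
compare_sequence_models <- function(windows_full, windows_reduced,
                                    specs = list(sequence_model_spec("gru"),
                                                 sequence_model_spec("lstm")),
                                    split = 0.7, latency_reps = 5L) {
  seeds <- vapply(specs, function(s) s$seed, 0L)
  if (length(unique(seeds)) != 1L)
    stop("contract error: all specs must share the split seed")
  sets <- list(full = windows_full, reduced = windows_reduced)
  rows <- list()
  models <- list()
  for (s in specs) {
    for (fs in names(sets)) {
      m <- train_sequence_model(sets[[fs]], s, split = split)
      lat <- evaluate_latency(m, sets[[fs]], latency_reps)
      r <- m$report
      rows[[paste(s$cell, fs)]] <- data.frame(
        model = s$cell, feature_set = fs,
        n_features = dim(sets[[fs]]$tensor)[1L],
        accuracy = r$accuracy, auc = r$auc, f1 = r$f1, recall = r$recall,
        latency_median_s = lat$median_s, stringsAsFactors = FALSE)
      models[[paste(s$cell, fs)]] <- m
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "models") <- models
  out
}
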