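.algos <- c("extra_trees", "gradient_boosting", "random_forest", "mlp")

#' Random up-sampling of the minority class
#'
#' Resamples the minority class with replacement until class counts are
#' equal. Applied to the training partition only; deterministic under the
#' seed.
#'
#' @param features numeric feature matrix (rows = windows).
#' @param labels character or factor vector (`"agitation"`/`"normal"`).
#' @param seed integer seed.
#' @return list `features`, `labels`, `index` (source row of every
#'   resampled row).
#' @export
upsample <- function(features, labels, seed = 1L) {
  labels <- as.character(labels)
  tab <- table(labels)
  if (length(tab) < 2L)
    stop("protocol error: up-sampling needs both classes present")
  minority <- names(tab)[which.min(tab)]
  need <- max(tab) - min(tab)
  idx <- seq_along(labels)
  if (need > 0) {
    src <- which(labels == minority)
    extra <- with_seed(seed, src[sample.int(length(src), need,
                                            replace = TRUE)])
    idx <- c(idx, extra)
  }
  list(features = features[idx, , drop = FALSE], labels = labels[idx],
       index = idx)
}

# drop all-NA columns, impute residual NAs with column medians (training
# medians are stored so test data is imputed consistently)
.prep_matrix <- function(features, manifest) {
  X <- as.matrix(features[, manifest, drop = FALSE])
  keep <- colSums(is.na(X)) < nrow(X)
  X <- X[, keep, drop = FALSE]
  med <- apply(X, 2L, function(c) stats::median(c, na.rm = TRUE))
  med[is.na(med)] <- 0
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- med[j]
  list(X = X, used = manifest[keep], medians = med)
}

#' Train a wristband classifier
#'
#' Four algorithms are supported, matching the evaluated model family:
#' `extra_trees` and `random_forest` (300-tree ensembles; Extra Trees uses
#' uniform-random split thresholds on the full sample, Random Forest
#' bootstrap sampling with histogram-best splits), `gradient_boosting`
#' (300 shallow trees, logistic loss, learning rate 0.1) and `mlp` (one
#' hidden layer of 100 rectified units, Adam, early stopping on a held-out
#' tenth of the training rows). Features are standardized internally for
#' the MLP. Deterministic under the seed.
#'
#' @param features training feature data.frame or matrix.
#' @param labels `"agitation"`/`"normal"` vector.
#' @param algo one of `r paste0('"', paste(.algos, collapse='", "'), '"')`.
#' @param manifest canonical feature name vector (defaults to the numeric
#'   columns of `features`).
#' @param seed integer seed.
#' @param ntree ensemble size (default 300).
#' @param hidden MLP hidden width (default 100).
#' @return object of class `agi_classifier` with elements `algo`, `fit`,
#'   `manifest`, `importance` (NULL for the MLP).
#' @export
train_classifier <- function(features, labels, algo = "extra_trees",
                             manifest = NULL, seed = 1L, ntree = 300L,
                             hidden = 100L) {
  algo <- match.arg(algo, .algos)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L)
    stop("protocol error: training needs both classes")
  if (min(table(labels)) < 10L)
    stop("protocol error: need at least 10 windows per class")
  if (is.null(manifest))
    manifest <- colnames(features)[vapply(as.data.frame(features),
                                          is.numeric, TRUE)]
  if (!all(manifest %in% colnames(features)))
    stop("contract error: feature/manifest mismatch")
  prep <- .prep_matrix(features, manifest)
  y <- as.integer(labels == "agitation")
  fit <- with_seed(seed, switch(algo,
    extra_trees = cpp_train_forest(prep$X, y, ntree,
                                   max(1L, floor(sqrt(ncol(prep$X)))),
                                   TRUE, 30L, 2L),
    random_forest = cpp_train_forest(prep$X, y, ntree,
                                     max(1L, floor(sqrt(ncol(prep$X)))),
                                     FALSE, 30L, 2L),
    gradient_boosting = cpp_train_gbm(prep$X, y, ntree, 0.1, 3L, 2L),
    mlp = {
      mu <- colMeans(prep$X)
      sdv <- apply(prep$X, 2L, stats::sd)
      sdv[sdv == 0] <- 1
      Z <- sweep(sweep(prep$X, 2L, mu), 2L, sdv, "/")
      m <- cpp_train_mlp(Z, y, hidden, 200L, 64L, 1e-3, 0.1, 10L)
      m$mu <- mu; m$sd <- sdv
      m
    }))
  imp <- NULL
  if (algo != "mlp") {
    imp <- stats::setNames(rep(0, length(manifest)), manifest)
    imp[prep$used] <- as.numeric(fit$importance)
  }
  structure(list(algo = algo, fit = fit, manifest = manifest,
                 used = prep$used, medians = prep$medians,
                 importance = imp, seed = seed),
            class = "agi_classifier")
}

#' Predict agitation probabilities
#' @param object an `agi_classifier`.
#' @param features feature data.frame/matrix with the training manifest's
#'   columns.
#' @param ... unused.
#' @return numeric vector of agitation probabilities.
#' @export
predict.agi_classifier <- function(object, features, ...) {
  X <- as.matrix(as.data.frame(features)[, object$used, drop = FALSE])
  for (j in seq_len(ncol(X)))
    X[is.na(X[, j]), j] <- object$medians[j]
  switch(object$algo,
    extra_trees = ,
    random_forest = as.numeric(cpp_predict_forest(object$fit, X)),
    gradient_boosting = as.numeric(cpp_predict_gbm(object$fit, X)),
    mlp = {
      Z <- sweep(sweep(X, 2L, object$fit$mu), 2L, object$fit$sd, "/")
      as.numeric(cpp_predict_mlp(object$fit, Z))
    })
}

#' Build a metrics report from labels and scores
#'
#' @param labels true `"agitation"`/`"normal"` (or 0/1) labels.
#' @param scores predicted probabilities.
#' @param threshold decision threshold (default 0.5).
#' @param algo,participant_id report metadata.
#' @param n_train training-set size recorded on the report.
#' @return data.frame of class `metrics_report` with accuracy, auc, recall,
#'   precision, f1 and the confusion counts.
#' @export
metrics_report <- function(labels, scores, threshold = 0.5, algo = NA,
                           participant_id = "all", n_train = NA_integer_) {
  y <- if (is.numeric(labels)) as.integer(labels)
       else as.integer(labels == "agitation")
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & y == 1L); tn <- sum(pred == 0L & y == 0L)
  fp <- sum(pred == 1L & y == 0L); fn <- sum(pred == 0L & y == 1L)
  out <- data.frame(
    participant_id = participant_id, algo = algo,
    accuracy = (tp + tn) / length(y),
    auc = auc_score(y, scores),
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    tp = tp, tn = tn, fp = fp, fn = fn,
    n_train = n_train, n_test = length(y),
    stringsAsFactors = FALSE)
  out$f1 <- with(out, ifelse(is.na(recall) | is.na(precision) |
                               recall + precision == 0, NA_real_,
                             2 * precision * recall / (precision + recall)))
  class(out) <- c("metrics_report", "data.frame")
  out
}

# stratified index split: returns list(train=, test=)
stratified_split <- function(labels, train_frac, seed) {
  if (train_frac <= 0 || train_frac >= 1)
    stop("protocol error: split fraction must be in (0, 1)")
  with_seed(seed, {
    tr <- integer()
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      k <- max(1L, round(length(idx) * train_frac))
      if (k >= length(idx)) k <- length(idx) - 1L
      tr <- c(tr, sample(idx, k))
    }
    tr <- sort(tr)
    list(train = tr, test = setdiff(seq_along(labels), tr))
  })
}

#' Labeled minute-window feature table for one recording
#'
#' Convenience wrapper: preprocess, segment into one-minute windows,
#' extract the canonical feature manifest and label the windows from the
#' episode table.
#'
#' @param physio list with `stream` and `labels` (one participant's
#'   recording, e.g. one element of a [generate_cohort()] bundle).
#' @param merge_preagitation label pre-agitation windows as agitation
#'   (early-warning training mode).
#' @return labeled feature data.frame (one row per minute window).
#' @export
participant_feature_table <- function(physio, merge_preagitation = FALSE) {
  pre <- preprocess_stream(physio$stream)
  win <- segment_windows(pre, 60, 60)
  fm <- extract_features(pre, win)
  label_windows(fm, physio$labels,
                preagitation = if (merge_preagitation) "merge" else "exclude")
}

# binary-training view: drop held-out pre-agitation windows
.binary_rows <- function(tab) {
  tab[tab$label %in% c("agitation", "normal"), , drop = FALSE]
}

#' Personalized training protocol
#'
#' Per participant and algorithm: a stratified random 70/30 split of that
#' participant's labeled windows, up-sampling of the training partition,
#' fitting, then evaluation on the untouched test partition. Participants
#' lacking agitation windows are skipped with a warning.
#'
#' @param tables named list (by participant) of labeled feature tables as
#'   produced by [participant_feature_table()].
#' @param algos algorithms to run (default all four).
#' @param split train fraction (default 0.7).
#' @param seed integer seed; split and fit seeds are derived from it.
#' @return `metrics_report` rows, one per participant x algorithm.
#' @export
run_personalized_protocol <- function(tables, algos = .algos, split = 0.7,
                                      seed = 1L) {
  manifest <- physio_feature_manifest()
  out <- list()
  for (pid in names(tables)) {
    tab <- .binary_rows(tables[[pid]])
    if (length(unique(tab$label)) < 2L) {
      warning("participant ", pid, " has a single class; skipped")
      next
    }
    sp <- stratified_split(tab$label, split,
                           seed + match(pid, names(tables)))
    tr <- tab[sp$train, , drop = FALSE]
    te <- tab[sp$test, , drop = FALSE]
    up <- upsample(tr[, manifest, drop = FALSE], tr$label, seed)
    for (algo in algos) {
      fit <- train_classifier(up$features, up$labels, algo,
                              manifest = manifest, seed = seed)
      sc <- predict(fit, te)
      out[[paste(pid, algo)]] <- metrics_report(
        te$label, sc, algo = algo, participant_id = pid,
        n_train = length(up$labels))
    }
  }
  if (!length(out)) stop("protocol error: no participant had both classes")
  do.call(rbind, out)
}

#' General (pooled) training protocol
#'
#' Pools every participant's windows, performs one stratified 70/30 split,
#' up-samples the training partition and evaluates each algorithm on the
#' untouched pooled test partition (the cohort-level analogue of the
#' personalized protocol).
#'
#' @inheritParams run_personalized_protocol
#' @return `metrics_report` rows, one per algorithm
#'   (`participant_id == "all"`).
#' @export
run_general_protocol <- function(tables, algos = .algos, split = 0.7,
                                 seed = 1L) {
  if (length(tables) < 2L)
    stop("protocol error: general model needs at least 2 participants")
  manifest <- physio_feature_manifest()
  pool <- do.call(rbind, lapply(names(tables), function(pid) {
    t <- .binary_rows(tables[[pid]]); t$participant_id <- pid; t
  }))
  sp <- stratified_split(pool$label, split, seed)
  tr <- pool[sp$train, , drop = FALSE]
  te <- pool[sp$test, , drop = FALSE]
  up <- upsample(tr[, manifest, drop = FALSE], tr$label, seed)
  out <- lapply(algos, function(algo) {
    fit <- train_classifier(up$features, up$labels, algo,
                            manifest = manifest, seed = seed)
    metrics_report(te$label, predict(fit, te), algo = algo,
                   participant_id = "all", n_train = length(up$labels))
  })
  do.call(rbind, out)
}

#' Compare algorithms across participants
#'
#' Per algorithm: mean, sample SD and t-based 95% confidence interval of
#' the per-participant accuracies and AUCs, plus a two-sided paired t-test
#' of each algorithm against the reference on the per-participant
#' accuracies. When all paired differences are zero the p-value is
#' reported as 1 with `exact_difference = TRUE`.
#'
#' @param reports output of [run_personalized_protocol()].
#' @param reference reference algorithm (default `"extra_trees"`).
#' @return data.frame, one row per algorithm, with columns
#'   `mean_accuracy`, `sd_accuracy`, `ci_lo_accuracy`, `ci_hi_accuracy`,
#'   the same for AUC, and `p_vs_reference`.
#' @export
compare_models <- function(reports, reference = "extra_trees") {
  algos <- unique(reports$algo)
  parts <- sort(unique(reports$participant_id))
  get <- function(a, metric) {
    sub <- reports[reports$algo == a, , drop = FALSE]
    if (!identical(sort(sub$participant_id), parts))
      stop("contract error: unequal participant sets across algorithms")
    sub[match(parts, sub$participant_id), metric]
  }
  if (length(parts) < 3L)
    stop("protocol error: need at least 3 participants for comparison")
  ref_acc <- get(reference, "accuracy")
  rows <- lapply(algos, function(a) {
    acc <- get(a, "accuracy"); auc <- get(a, "auc")
    ci <- function(x) {
      m <- mean(x); s <- stats::sd(x)
      half <- stats::qt(0.975, length(x) - 1L) * s / sqrt(length(x))
      c(m, s, m - half, m + half)
    }
    ca <- ci(acc); cu <- ci(auc)
    d <- acc - ref_acc
    exact <- all(abs(d - d[1L]) < 1e-12)
    p <- if (a == reference) NA_real_
         else if (exact) {
           if (abs(mean(d)) < 1e-12) 1.0 else 0.0
         } else stats::t.test(acc, ref_acc, paired = TRUE)$p.value
    data.frame(algo = a, mean_accuracy = ca[1L], sd_accuracy = ca[2L],
               ci_lo_accuracy = ca[3L], ci_hi_accuracy = ca[4L],
               mean_auc = cu[1L], sd_auc = cu[2L], ci_lo_auc = cu[3L],
               ci_hi_auc = cu[4L], p_vs_reference = p,
               exact_difference = exact && a != reference,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
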