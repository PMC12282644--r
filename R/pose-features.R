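#' Canonical pose feature manifest
#'
#' The geometric feature set over 14 skeletal keypoints (keypoint 1 is the
#' neck/torso reference point): `eu_k` (k = 1..14), the Euclidean
#' displacement of keypoint k between consecutive frames in pixels;
#' `eu_1_j` (j = 3..14), the Euclidean distance from keypoint 1 to
#' keypoint j; `por_i_1` (i = 2..14), the point-of-reference value of
#' keypoint i — its trunk-normalized (hence scale-invariant) distance from
#' keypoint 1; and `ang_1_j` (j = 2..14), the angle of keypoint j about
#' keypoint 1 against the image horizontal, in degrees in `[0, 360)` with
#' "up" at 90. The enumeration yields 52 names; a configuration list may
#' restrict it.
#'
#' @return character vector of 52 feature names in canonical order.
#' @export
pose_feature_manifest <- function() {
  c(paste0("eu_", 1:14),
    paste0("eu_1_", 3:14),
    paste0("por_", 2:14, "_1"),
    paste0("ang_1_", 2:14))
}

.frame_xy <- function(frame) {
  list(x = as.numeric(frame[paste0("x", 1:14)]),
       y = as.numeric(frame[paste0("y", 1:14)]),
       c = as.numeric(frame[paste0("c", 1:14)]))
}

.trunk_length <- function(x, y) {
  hx <- (x[9L] + x[10L]) / 2; hy <- (y[9L] + y[10L]) / 2
  sqrt((x[1L] - hx)^2 + (y[1L] - hy)^2)
}

#' Normalize a pose frame for camera and position variation
#'
#' Translates so keypoint 1 (the torso/neck root) sits at the origin and
#' scales by the trunk length (distance from keypoint 1 to the hip
#' midpoint), making the coordinates dimensionless and invariant to
#' similarity transforms of the camera frame. The original pixel-space
#' frame should be retained for the pixel-space displacement features.
#'
#' @param frame one-row pose data.frame (`x1..x14`, `y1..y14`, `c1..c14`).
#' @return the frame with normalized coordinates; `attr(, "usable")` is
#'   `FALSE` when keypoint 1 is missing or the trunk length is zero.
#' @export
normalize_pose <- function(frame) {
  p <- .frame_xy(frame)
  usable <- p$c[1L] > 0
  trunk <- .trunk_length(p$x, p$y)
  if (!usable || !is.finite(trunk) || trunk <= 0) {
    attr(frame, "usable") <- FALSE
    return(frame)
  }
  for (j in 1:14) {
    frame[[paste0("x", j)]] <- (p$x[j] - p$x[1L]) / trunk
    frame[[paste0("y", j)]] <- (p$y[j] - p$y[1L]) / trunk
  }
  attr(frame, "usable") <- TRUE
  frame
}

#' Geometric features for one consecutive frame pair
#'
#' Computes the canonical manifest ([pose_feature_manifest()]) for the
#' current frame given the previous frame: pixel-space displacements
#' `eu_k`, root-relative distances `eu_1_j`, trunk-normalized
#' point-of-reference values `por_i_1`, and angles `ang_1_j` about the
#' reference keypoint (degrees, `[0, 360)`, up = 90). Features involving a
#' keypoint with confidence 0 are `NA`.
#'
#' @param prev,curr one-row pose data.frames for the same person at
#'   consecutive frames.
#' @return named numeric vector of 52 features.
#' @export
extract_pose_features <- function(prev, curr) {
  if (!identical(as.character(prev$person_id), as.character(curr$person_id)))
    stop("contract error: frames belong to different persons")
  a <- .frame_xy(prev); b <- .frame_xy(curr)
  miss_b <- b$c == 0; miss_a <- a$c == 0
  trunk <- .trunk_length(b$x, b$y)
  out <- stats::setNames(rep(NA_real_, 52L), pose_feature_manifest())
  for (k in 1:14) {
    if (!miss_a[k] && !miss_b[k])
      out[paste0("eu_", k)] <- sqrt((b$x[k] - a$x[k])^2 +
                                      (b$y[k] - a$y[k])^2)
  }
  root_ok <- !miss_b[1L]
  for (j in 3:14) {
    if (root_ok && !miss_b[j])
      out[paste0("eu_1_", j)] <- sqrt((b$x[j] - b$x[1L])^2 +
                                        (b$y[j] - b$y[1L])^2)
  }
  for (i in 2:14) {
    if (root_ok && !miss_b[i] && is.finite(trunk) && trunk > 0)
      out[paste0("por_", i, "_1")] <-
        sqrt((b$x[i] - b$x[1L])^2 + (b$y[i] - b$y[1L])^2) / trunk
  }
  for (j in 2:14) {
    if (root_ok && !miss_b[j]) {
      # image y grows downward; flip so "up" maps to 90 degrees
      ang <- atan2(-(b$y[j] - b$y[1L]), b$x[j] - b$x[1L]) * 180 / pi
      out[paste0("ang_1_", j)] <- ang %% 360
    }
  }
  out
}

#' Per-frame pose feature matrix for a stream
#'
#' Vectorized computation of [extract_pose_features()] over an entire
#' keypoint stream. The first frame has no predecessor; its displacement
#' features are back-filled from the second frame so every frame carries a
#' complete row.
#'
#' @param frames wide pose data.frame from [generate_pose()] or
#'   [read_pose_jsonl()].
#' @return data.frame: `time`, then the 52 manifest features, one row per
#'   frame.
#' @export
pose_feature_matrix <- function(frames) {
  n <- nrow(frames)
  X <- as.matrix(frames[, paste0("x", 1:14)])
  Y <- as.matrix(frames[, paste0("y", 1:14)])
  C <- as.matrix(frames[, paste0("c", 1:14)])
  miss <- C == 0
  M <- matrix(NA_real_, n, 52L, dimnames = list(NULL,
                                                pose_feature_manifest()))
  dX <- rbind(NA, diff(X)); dY <- rbind(NA, diff(Y))
  for (k in 1:14) {
    v <- sqrt(dX[, k]^2 + dY[, k]^2)
    v[miss[, k]] <- NA
    v[c(FALSE, miss[-n, k])] <- NA
    M[, paste0("eu_", k)] <- v
  }
  M[1L, 1:14] <- M[2L, 1:14]                 # back-fill first frame
  trunk <- sqrt((X[, 1L] - (X[, 9L] + X[, 10L]) / 2)^2 +
                  (Y[, 1L] - (Y[, 9L] + Y[, 10L]) / 2)^2)
  for (j in 2:14) {
    dx <- X[, j] - X[, 1L]; dy <- Y[, j] - Y[, 1L]
    d <- sqrt(dx^2 + dy^2)
    d[miss[, j] | miss[, 1L]] <- NA
    if (j >= 3L) M[, paste0("eu_1_", j)] <- d
    M[, paste0("por_", j, "_1")] <- d / ifelse(trunk > 0, trunk, NA)
    ang <- (atan2(-dy, dx) * 180 / pi) %% 360
    ang[miss[, j] | miss[, 1L]] <- NA
    M[, paste0("ang_1_", j)] <- ang
  }
  cbind(data.frame(time = frames$time), as.data.frame(M))
}

#' Correlation-threshold feature reduction
#'
#' Iterates features in canonical (column) order and drops any feature
#' whose absolute Pearson correlation with an already-retained feature
#' exceeds the threshold; after reduction no retained pair exceeds it.
#' Constant features have undefined correlation, which is treated as 0, so
#' they are retained unless they duplicate an earlier column exactly.
#'
#' @param mat numeric matrix (rows = frames or windows, named columns).
#' @param threshold correlation threshold in (0, 1); default 0.8.
#' @return character vector of retained feature names in canonical order.
#' @export
reduce_features <- function(mat, threshold = 0.8) {
  stopifnot(threshold > 0, threshold < 1, nrow(mat) >= 2L)
  mat <- as.matrix(mat)
  sds <- apply(mat, 2L, stats::sd)
  cm <- suppressWarnings(abs(stats::cor(mat,
                                        use = "pairwise.complete.obs")))
  cm[is.na(cm)] <- 0
  keep <- character()
  keep_idx <- integer()
  for (j in seq_len(ncol(mat))) {
    drop <- FALSE
    for (k in keep_idx) {
      if (cm[j, k] > threshold ||
          (sds[j] == 0 && sds[k] == 0 &&
             isTRUE(all.equal(mat[, j], mat[, k])))) {
        drop <- TRUE
        break
      }
    }
    if (!drop) {
      keep <- c(keep, colnames(mat)[j])
      keep_idx <- c(keep_idx, j)
    }
  }
  keep
}

#' Build labeled sliding sequence windows
#'
#' Windows `[k*stride, k*stride + window)` for
#' `k = 0 .. floor((T - window)/stride)` where `T` is the stream duration
#' `n_frames / fps`. Each window is labeled by the >= 50% overlap rule;
#' windows in which more than `max_missing` of the frames have missing
#' features are dropped, and remaining missing values are imputed by
#' last-observation-carried-forward (back-filled at the window head).
#'
#' @param features per-frame feature data.frame from
#'   [pose_feature_matrix()].
#' @param episodes an [episode_labels()] table.
#' @param window_s window length in seconds (default 30).
#' @param stride_s stride in seconds (default 1).
#' @param fps frames per second of the stream.
#' @param feature_names manifest subset to keep (default: all 52).
#' @param max_missing tolerated fraction of missing frames (default 0.2).
#' @param merge_preagitation merge pre-agitation intervals into the
#'   positive class (passed to the labeling rule).
#' @return object of class `pose_windows`: list with `starts`, `labels`,
#'   `tensor` (array `features x frames x windows`) and `feature_names`.
#' @export
build_windows <- function(features, episodes, window_s = 30, stride_s = 1,
                          fps = 15, feature_names = pose_feature_manifest(),
                          max_missing = 0.2, merge_preagitation = FALSE) {
  n <- nrow(features)
  T_s <- n / fps
  if (T_s < window_s)
    return(structure(list(starts = numeric(), labels = character(),
                          tensor = array(0, c(length(feature_names), 0, 0)),
                          feature_names = feature_names,
                          window_s = window_s, stride_s = stride_s,
                          fps = fps),
                     class = "pose_windows"))
  ks <- 0:floor((T_s - window_s) / stride_s)
  starts <- features$time[1L] + ks * stride_s
  wl <- round(window_s * fps)
  Fm <- t(as.matrix(features[, feature_names, drop = FALSE]))
  lab <- label_windows(data.frame(window_start = starts,
                                  window_end = starts + window_s),
                       episodes,
                       preagitation = if (merge_preagitation) "merge"
                                      else "exclude")
  keep <- logical(length(starts))
  slabs <- character(length(starts))
  tens <- array(NA_real_, c(length(feature_names), wl, length(starts)))
  t0 <- features$time[1L]
  for (w in seq_along(starts)) {
    i0 <- round((starts[w] - t0) * fps) + 1L
    idx <- i0:(i0 + wl - 1L)
    if (max(idx) > n) next
    sub <- Fm[, idx, drop = FALSE]
    frac_miss <- mean(apply(is.na(sub), 2L, any))
    if (frac_miss > max_missing) next
    if (anyNA(sub)) sub <- t(apply(sub, 1L, .locf))
    keep[w] <- TRUE
    tens[, , w] <- sub
    slabs[w] <- lab$label[w]
  }
  structure(list(starts = starts[keep], labels = slabs[keep],
                 tensor = tens[, , keep, drop = FALSE],
                 feature_names = feature_names,
                 window_s = window_s, stride_s = stride_s, fps = fps),
            class = "pose_windows")
}

.locf <- function(v) {
  if (!anyNA(v)) return(v)
  ok <- which(!is.na(v))
  if (!length(ok)) return(rep(0, length(v)))
  idx <- cumsum(!is.na(v))
  filled <- v[ok][pmax(1L, idx)]
  filled
}

#' @export
print.pose_windows <- function(x, ...) {
  cat("<pose_windows>", length(x$starts), "windows x",
      dim(x$tensor)[2L], "frames x", dim(x$tensor)[1L], "features;",
      sum(x$labels == "agitation"), "agitation\n")
  invisible(x)
}
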