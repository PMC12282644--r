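#' Preprocess a raw physiological stream
#'
#' Per channel: clip values to the physiological range, fill gaps up to
#' `max_gap_s` seconds by linear interpolation on the channel's regular
#' grid (longer gaps are marked unusable and excluded from windowing),
#' low-pass filter electrodermal activity at 1 Hz and temperature at
#' 0.1 Hz with zero-phase filters, and add the derived `acc_mag` channel
#' `sqrt(x^2 + y^2 + z^2)`.
#'
#' @param stream a [physio_stream()].
#' @param max_gap_s longest gap (seconds) bridged by interpolation.
#' @return a preprocessed [physio_stream()]; attribute `unusable` holds,
#'   per channel, a data.frame of `[start, end)` spans excluded from use.
#' @export
preprocess_stream <- function(stream, max_gap_s = 5) {
  stopifnot(inherits(stream, "physio_stream"))
  ranges <- list(eda = c(0.01, 100), temp = c(20, 45), pulse = c(20, 250),
                 acc_x = c(-16, 16), acc_y = c(-16, 16), acc_z = c(-16, 16))
  cutoffs <- c(eda = 1, temp = 0.1)
  unusable <- list()
  chans <- stream$channels
  for (nm in names(chans)) {
    ch <- chans[[nm]]
    d <- ch$data
    if (nm %in% names(ranges))
      d$value <- pmin(ranges[[nm]][2L], pmax(ranges[[nm]][1L], d$value))
    # regularize on the channel grid; interpolate short gaps only
    dt <- 1 / ch$rate
    grid <- seq(d$time[1L], d$time[nrow(d)], by = dt)
    gi <- stats::approx(d$time, d$value, xout = grid, method = "linear")$y
    gaps <- which(diff(d$time) > dt * 1.5)
    bad <- data.frame(start = numeric(), end = numeric())
    for (g in gaps) {
      glen <- d$time[g + 1L] - d$time[g]
      if (glen > max_gap_s)
        bad <- rbind(bad, data.frame(start = d$time[g], end = d$time[g + 1L]))
    }
    if (nm %in% names(cutoffs) && ch$rate > 2 * cutoffs[[nm]])
      gi <- lowpass_zero_phase(gi, ch$rate, cutoffs[[nm]])
    chans[[nm]] <- list(rate = ch$rate,
                        data = data.frame(time = grid, value = gi))
    unusable[[nm]] <- bad
  }
  if (all(c("acc_x", "acc_y", "acc_z") %in% names(chans))) {
    ax <- chans$acc_x$data; ay <- chans$acc_y$data; az <- chans$acc_z$data
    n <- min(nrow(ax), nrow(ay), nrow(az))
    chans$acc_mag <- list(rate = chans$acc_x$rate,
                          data = data.frame(
                            time = ax$time[seq_len(n)],
                            value = sqrt(ax$value[seq_len(n)]^2 +
                                           ay$value[seq_len(n)]^2 +
                                           az$value[seq_len(n)]^2)))
    unusable$acc_mag <- unique(rbind(unusable$acc_x, unusable$acc_y,
                                     unusable$acc_z))
  }
  out <- physio_stream(stream$participant_id, chans)
  attr(out, "unusable") <- unusable
  out
}

#' Decompose electrodermal activity into tonic and phasic components
#'
#' The tonic (slow, sympathetic-level) component is the zero-phase low-pass
#' part of the signal below `cutoff_hz`; the phasic (burst) component is
#' the residual, so `tonic + phasic == eda` holds pointwise by
#' construction.
#'
#' @param values numeric EDA series (regularly sampled, preprocessed).
#' @param rate sampling rate in Hz.
#' @param cutoff_hz tonic cutoff, default 0.05 Hz.
#' @return list with numeric `tonic` and `phasic` vectors.
#' @export
decompose_eda <- function(values, rate, cutoff_hz = 0.05) {
  if (length(values) < 60 * rate)
    stop("precondition error: EDA series must cover at least 60 s")
  tonic <- lowpass_zero_phase(values, rate, cutoff_hz)
  list(tonic = tonic, phasic = values - tonic)
}

#' Segment a stream into fixed windows
#'
#' Windows are `[t0 + k*stride, t0 + k*stride + window)` for
#' `k = 0 .. floor((T - window)/stride)` where `t0` is the earliest sample
#' time and `T` the covered span. Windows intersecting an unusable span
#' (long gap) are dropped and counted.
#'
#' @param stream a preprocessed [physio_stream()].
#' @param window_s window length (seconds), default 60.
#' @param stride_s stride (seconds), default 60.
#' @return data.frame with `window_start`, `window_end`; attribute
#'   `n_dropped` counts windows removed for unusable spans.
#' @export
segment_windows <- function(stream, window_s = 60, stride_s = 60) {
  stopifnot(window_s > 0, stride_s > 0)
  t0 <- min(vapply(stream$channels, function(ch) ch$data$time[1L], 0))
  t1 <- max(vapply(stream$channels,
                   function(ch) ch$data$time[nrow(ch$data)], 0))
  T <- t1 - t0
  if (T < window_s) {
    warning("stream shorter than one window; no windows emitted")
    out <- data.frame(window_start = numeric(), window_end = numeric())
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  k <- 0:floor((T - window_s) / stride_s)
  ws <- t0 + k * stride_s
  out <- data.frame(window_start = ws, window_end = ws + window_s)
  bad <- attr(stream, "unusable")
  drop <- rep(FALSE, nrow(out))
  if (!is.null(bad)) {
    for (b in bad) {
      if (!nrow(b)) next
      for (i in seq_len(nrow(b)))
        drop <- drop | (out$window_start < b$end[i] &
                          out$window_end > b$start[i])
    }
  }
  res <- out[!drop, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_dropped") <- sum(drop)
  res
}

.stat_names <- c("mean", "sd", "min", "max", "median", "iqr", "skewness",
                 "kurtosis")
.time_names <- c("rms", "energy", "zero_crossings", "mean_abs_diff",
                 "line_length", "slope")

# per-channel feature domain plan; bands limited by each channel's Nyquist
.channel_plan <- function() {
  list(
    acc_x  = list(freq = FALSE, tf = FALSE),
    acc_y  = list(freq = FALSE, tf = FALSE),
    acc_z  = list(freq = FALSE, tf = FALSE),
    acc_mag = list(freq = TRUE, bands = c("0-0.5", "0.5-2", "2-5"), tf = TRUE),
    eda    = list(freq = TRUE, bands = c("0-0.5", "0.5-2"), tf = TRUE),
    eda_tonic = list(freq = FALSE, tf = FALSE),
    eda_phasic = list(freq = TRUE, bands = c("0-0.5", "0.5-2"), tf = TRUE),
    temp   = list(freq = TRUE, bands = "0-0.5", tf = FALSE),
    pulse  = list(freq = FALSE, tf = FALSE)
  )
}

#' Canonical physiological feature manifest
#'
#' The multi-domain feature list is fixed per channel: statistical
#' (mean, sd, min, max, median, iqr, skewness, kurtosis) and time-domain
#' (rms, energy, zero crossings of the mean-removed signal, mean absolute
#' first difference, line length, least-squares slope) features for every
#' channel; Welch frequency-domain features (dominant frequency, total
#' power, band powers where the sampling rate permits, spectral entropy)
#' and Daubechies-4 wavelet features (4 detail-band energies, approximation
#' energy, 4 energy ratios) for the dynamics-bearing channels. Pulse, the
#' slow tonic component and the individual accelerometer axes carry
#' statistical and time-domain features only. The manifest is emitted with
#' every run so feature matrices are comparable across runs.
#'
#' @return character vector of feature names
#'   (`<channel>_<domain>_<statistic>`), in canonical order.
#' @export
physio_feature_manifest <- function() {
  plan <- .channel_plan()
  out <- character()
  for (nm in names(plan)) {
    p <- plan[[nm]]
    out <- c(out, paste0(nm, "_stat_", .stat_names),
             paste0(nm, "_time_", .time_names))
    if (isTRUE(p$freq))
      out <- c(out, paste0(nm, "_freq_",
                           c("dominant", "total_power",
                             paste0("band_", gsub("[-.]", "_", p$bands)),
                             "spectral_entropy")))
    if (isTRUE(p$tf))
      out <- c(out, paste0(nm, "_tf_",
                           c(paste0("energy_d", 1:4), "energy_a4",
                             paste0("ratio_d", 1:4))))
  }
  out
}

.channel_features <- function(x, rate, plan) {
  n <- length(x)
  m <- mean(x); s <- stats::sd(x)
  if (n < 2L) s <- 0
  sh <- moment_shape(x)
  stat <- c(m, s, min(x), max(x), stats::median(x),
            stats::IQR(x), sh[["skewness"]], sh[["kurtosis"]])
  xc <- x - m
  zc <- if (n > 1L) sum(diff(sign(xc)[sign(xc) != 0]) != 0) else 0
  slope <- if (n > 1L) {
    tt <- (seq_len(n) - 1) / rate
    sum((tt - mean(tt)) * xc) / sum((tt - mean(tt))^2)
  } else 0
  tim <- c(sqrt(mean(x^2)), sum(x^2), zc,
           if (n > 1L) mean(abs(diff(x))) else 0,
           if (n > 1L) sum(abs(diff(x))) else 0,
           slope)
  out <- c(stat, tim)
  if (isTRUE(plan$freq)) {
    if (s > 0 && n >= 8L) {
      w <- welch_psd(x, rate)
      pw <- w$psd; fr <- w$freq
      tot <- sum(pw)
      dom <- fr[which.max(pw)]
      bands <- vapply(plan$bands, function(b) {
        lim <- as.numeric(strsplit(b, "-")[[1L]])
        sum(pw[fr >= lim[1L] & fr < lim[2L]])
      }, 0)
      p_norm <- pw / tot
      p_norm <- p_norm[p_norm > 0]
      ent <- -sum(p_norm * log(p_norm)) / log(length(pw))
      out <- c(out, dom, tot, bands, ent)
    } else {
      out <- c(out, rep(0, 3L + length(plan$bands)))
    }
  }
  if (isTRUE(plan$tf)) {
    if (n >= 16L) {
      en <- dwt_energies(x - m, 4L)
      tot <- sum(en)
      ratio <- if (tot > 0) en[1:4] / tot else rep(0, 4L)
      out <- c(out, en, ratio)
    } else {
      out <- c(out, rep(0, 9L))
    }
  }
  out
}

#' Extract the multi-domain feature matrix for a stream
#'
#' Runs EDA decomposition, slices every channel into the given windows and
#' computes the canonical manifest ([physio_feature_manifest()]) per
#' window. Missing channels yield `NA` columns (excluded later by the
#' model layer).
#'
#' @param stream a preprocessed [physio_stream()] (see
#'   [preprocess_stream()]).
#' @param windows data.frame from [segment_windows()].
#' @return data.frame: `window_start`, `window_end`, then one column per
#'   manifest feature; attribute `manifest` holds the feature name vector.
#' @export
extract_features <- function(stream, windows) {
  chans <- stream$channels
  if ("eda" %in% names(chans) && !"eda_tonic" %in% names(chans)) {
    dec <- decompose_eda(chans$eda$data$value, chans$eda$rate)
    chans$eda_tonic <- list(rate = chans$eda$rate,
                            data = data.frame(time = chans$eda$data$time,
                                              value = dec$tonic))
    chans$eda_phasic <- list(rate = chans$eda$rate,
                             data = data.frame(time = chans$eda$data$time,
                                               value = dec$phasic))
  }
  plan <- .channel_plan()
  manifest <- physio_feature_manifest()
  nw <- nrow(windows)
  M <- matrix(NA_real_, nw, length(manifest),
              dimnames = list(NULL, manifest))
  for (nm in names(plan)) {
    if (!nm %in% names(chans)) next
    ch <- chans[[nm]]
    tv <- ch$data$time; vv <- ch$data$value
    cols <- grep(paste0("^", nm, "_(stat|time|freq|tf)_"), manifest)
    los <- findInterval(windows$window_start - 1e-9, tv) + 1L
    his <- findInterval(windows$window_end - 1e-9, tv)
    for (i in seq_len(nw)) {
      if (his[i] < los[i]) next
      M[i, cols] <- .channel_features(vv[los[i]:his[i]], ch$rate, plan[[nm]])
    }
  }
  out <- cbind(windows[, c("window_start", "window_end")], as.data.frame(M))
  attr(out, "manifest") <- manifest
  out
}

#' Rank features by model importance
#'
#' Orders the trained model's impurity-based importances descending; ties
#' are broken by canonical manifest order. Models without native
#' importances (the MLP) are ranked by permutation importance: the drop
#' in AUC when one feature column is shuffled, averaged over repeats,
#' which requires labeled evaluation data.
#'
#' @param model a model from [train_classifier()].
#' @param manifest feature name vector in canonical order (defaults to the
#'   model's stored manifest).
#' @param features,labels labeled evaluation data, needed only when the
#'   model has no native importances.
#' @param n_repeats shuffles per feature for permutation importance.
#' @param seed RNG seed for the permutation path.
#' @return data.frame `feature`, `importance`, sorted.
#' @export
rank_features <- function(model, manifest = model$manifest,
                          features = NULL, labels = NULL,
                          n_repeats = 3L, seed = 1L) {
  imp <- model$importance
  if (is.null(imp)) {
    if (is.null(features) || is.null(labels))
      stop("model has no native importances; supply features and labels ",
           "for permutation importance")
    y <- as.integer(as.character(labels) == "agitation")
    base <- auc_score(y, predict(model, features))
    imp <- with_seed(seed, vapply(manifest, function(nm) {
      drops <- vapply(seq_len(n_repeats), function(r) {
        shuf <- features
        shuf[[nm]] <- sample(shuf[[nm]])
        base - auc_score(y, predict(model, shuf))
      }, 0)
      mean(drops)
    }, 0))
  }
  stopifnot(length(imp) == length(manifest))
  ord <- order(-imp, seq_along(manifest))
  data.frame(feature = manifest[ord], importance = imp[ord],
             row.names = NULL, stringsAsFactors = FALSE)
}
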