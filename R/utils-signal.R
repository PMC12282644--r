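#' @useDynLib agiwatch, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft approx median quantile sd var coef lm qt pt rnorm
#'   runif rbinom predict t.test setNames
#' @importFrom utils read.csv write.csv head tail
NULL

#' Zero-phase low-pass filter
#'
#' Brick-wall low-pass in the frequency domain, applied after removing a
#' least-squares linear trend and mirror-padding the series so ramps and
#' edges survive filtering. The trend is added back afterwards, so a pure
#' linear drift (and any constant) passes unchanged; components above the
#' cutoff are removed with no phase shift.
#'
#' @param x numeric vector, regularly sampled.
#' @param fs sampling rate in Hz.
#' @param cutoff cutoff frequency in Hz.
#' @return filtered numeric vector, same length as `x`.
#' @keywords internal
lowpass_zero_phase <- function(x, fs, cutoff) {
  n <- length(x)
  if (n < 3L || cutoff >= fs / 2) return(x)
  idx <- seq_len(n)
  fit <- stats::lsfit(idx, x)
  trend <- fit$coefficients[1L] + fit$coefficients[2L] * idx
  r <- x - trend
  # mirror padding: [rev(r), r, rev(r)] keeps the padded series continuous
  pad <- rev(r)
  xp <- c(pad, r, pad)
  np <- length(xp)
  f <- (seq_len(np) - 1L) / np * fs
  f <- pmin(f, fs - f)              # two-sided frequency axis
  keep <- as.numeric(f <= cutoff)
  filt <- Re(stats::fft(stats::fft(xp) * keep, inverse = TRUE)) / np
  filt[(n + 1L):(2L * n)] + trend
}

#' Welch power spectral density
#'
#' Hann-windowed, 50%-overlapping segment averaging. Returns one-sided PSD.
#'
#' @param x numeric vector (demeaned internally).
#' @param fs sampling rate (Hz).
#' @param seg_len segment length in samples; defaults to
#'   `min(length(x), 32 * fs)`.
#' @return list with `freq` and `psd` vectors.
#' @keywords internal
welch_psd <- function(x, fs, seg_len = NULL) {
  n <- length(x)
  if (is.null(seg_len)) seg_len <- min(n, max(8L, round(32 * fs)))
  seg_len <- min(seg_len, n)
  x <- x - mean(x)
  step <- max(1L, floor(seg_len / 2))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, seg_len - 1) / (seg_len - 1))
  u <- sum(w^2)
  nf <- floor(seg_len / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)] * w
    p <- Mod(stats::fft(seg))^2 / (u * fs)
    acc <- acc + p[seq_len(nf)]
  }
  psd <- acc / length(starts)
  # one-sided: double interior bins
  if (nf > 2L) psd[2:(nf - 1L)] <- 2 * psd[2:(nf - 1L)]
  list(freq = (seq_len(nf) - 1L) * fs / seg_len, psd = psd)
}

# Daubechies-4 (4-tap) analysis filters.
.db4_lo <- c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2))
.db4_hi <- rev(.db4_lo) * c(1, -1, 1, -1)

#' Discrete wavelet sub-band energies
#'
#' Daubechies-4 DWT with periodic boundary handling. Returns detail energies
#' d1..d`levels` (finest to coarsest) and the final approximation energy.
#'
#' @param x numeric vector; must have at least `2^levels` samples.
#' @param levels decomposition depth (default 4).
#' @return named numeric vector `d1..d<levels>, a<levels>` of energies
#'   (sums of squared coefficients).
#' @keywords internal
dwt_energies <- function(x, levels = 4L) {
  out <- numeric(levels + 1L)
  names(out) <- c(paste0("d", seq_len(levels)), paste0("a", levels))
  a <- x
  for (lev in seq_len(levels)) {
    n <- length(a)
    if (n < 4L) {                      # too short: remaining bands empty
      out[length(out)] <- sum(a^2)
      return(out)
    }
    ap <- c(a, a[seq_len(3L)])         # periodic extension
    idx <- seq(1L, n, by = 2L)
    lo <- hi <- numeric(length(idx))
    for (k in 0:3) {
      lo <- lo + .db4_lo[k + 1L] * ap[idx + k]
      hi <- hi + .db4_hi[k + 1L] * ap[idx + k]
    }
    out[lev] <- sum(hi^2)
    a <- lo
  }
  out[levels + 1L] <- sum(a^2)
  out
}

#' Sample skewness and excess kurtosis (moment estimators)
#' @param x numeric vector.
#' @return named vector `skewness`, `kurtosis`; both 0 for constant input.
#' @keywords internal
moment_shape <- function(x) {
  n <- length(x)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 <= 0 || n < 3L) return(c(skewness = 0, kurtosis = 0))
  c(skewness = mean((x - m)^3) / s2^1.5,
    kurtosis = mean((x - m)^4) / s2^2 - 3)
}

#' Rank-based AUC (Mann-Whitney)
#' @param labels 0/1 vector (1 = positive class).
#' @param scores numeric scores, higher = more positive.
#' @return AUC in `[0, 1]`; `NA` if one class is absent.
#' @export
auc_score <- function(labels, scores) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
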