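make_stream <- function(..., rate = 4) {
  chans <- list(...)
  out <- lapply(chans, function(v)
    list(rate = rate, data = data.frame(time = (seq_along(v) - 1) / rate,
                                        value = v)))
  physio_stream("t", out)
}

test_that("preprocessing passes DC, fills short gaps, derives acc_mag", {
  s <- make_stream(eda = rep(5, 400))
  p <- preprocess_stream(s)
  expect_lt(max(abs(p$channels$eda$data$value - 5)), 1e-6)

  # 3-second gap in temp filled linearly
  tt <- c(0:10, 14:30)
  s2 <- physio_stream("t", list(temp = list(rate = 1,
    data = data.frame(time = tt, value = 33 + 0.1 * tt))))
  p2 <- preprocess_stream(s2)
  d <- p2$channels$temp$data
  expect_equal(nrow(d), 31L)
  expect_lt(max(abs(d$value - (33 + 0.1 * d$time))), 0.02)
  expect_equal(nrow(attr(p2, "unusable")$temp), 0L)

  # longer gap flagged unusable
  tt3 <- c(0:10, 25:40)
  s3 <- physio_stream("t", list(temp = list(rate = 1,
    data = data.frame(time = tt3, value = rep(33, length(tt3))))))
  p3 <- preprocess_stream(s3)
  expect_equal(nrow(attr(p3, "unusable")$temp), 1L)

  n <- 320
  s4 <- make_stream(acc_x = rep(0.6, n), acc_y = rep(0.8, n),
                    acc_z = rep(0, n), rate = 32)
  p4 <- preprocess_stream(s4)
  expect_lt(max(abs(p4$channels$acc_mag$data$value - 1)), 1e-9)
})

test_that("EDA decomposition: identity, recovery, degenerate input", {
  rate <- 4
  n <- 240 * rate
  tt <- (seq_len(n) - 1) / rate
  # constant input: tonic = input, phasic = 0
  d0 <- decompose_eda(rep(3, n), rate)
  expect_lt(max(abs(d0$tonic - 3)), 1e-9)
  expect_lt(max(abs(d0$phasic)), 1e-9)
  # ramp + 1 Hz sinusoid: components recovered within 5% RMS
  ramp <- 2 + 0.01 * tt
  sine <- 0.5 * sin(2 * pi * 1 * tt)
  d <- decompose_eda(ramp + sine, rate)
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(rms(d$tonic - ramp) / rms(ramp), 0.05)
  expect_lt(rms(d$phasic - sine) / rms(sine), 0.05)
  # identity holds for arbitrary input
  set.seed(3)
  x <- cumsum(rnorm(n))
  dx <- decompose_eda(x, rate)
  expect_lt(max(abs(dx$tonic + dx$phasic - x)), 1e-9)
  expect_error(decompose_eda(rnorm(10), 4), "at least 60 s")
})

test_that("window segmentation matches the closed form", {
  mk <- function(T, rate = 1) make_stream(temp = rep(33, T * rate + 1),
                                          rate = rate)
  expect_equal(nrow(segment_windows(mk(600))), 10L)
  expect_warning(w0 <- segment_windows(mk(59)), "shorter")
  expect_equal(nrow(w0), 0L)
  expect_equal(nrow(segment_windows(mk(125))), 2L)
  w <- segment_windows(mk(125))
  expect_equal(max(w$window_end), 120)
  # windows over unusable spans are dropped and counted
  tt <- c(0:100, 130:260)
  s <- physio_stream("t", list(temp = list(rate = 1,
    data = data.frame(time = tt, value = rep(33, length(tt))))))
  p <- preprocess_stream(s)
  w2 <- segment_windows(p)
  expect_gt(attr(w2, "n_dropped"), 0L)
})

test_that("feature extraction: constants, sinusoids, identities", {
  rate <- 4
  n <- 240
  win <- data.frame(window_start = 0, window_end = 60)
  s <- make_stream(eda = rep(5, n), rate = rate)
  f <- extract_features(preprocess_stream(s), win)
  expect_equal(f$eda_stat_sd, 0)
  expect_equal(f$eda_time_zero_crossings, 0)
  expect_equal(f$eda_freq_spectral_entropy, 0)

  tt <- (seq_len(n) - 1) / rate
  s2 <- make_stream(eda = 5 + sin(2 * pi * 1 * tt), rate = rate)
  f2 <- extract_features(preprocess_stream(s2), win)
  expect_lt(abs(f2$eda_freq_dominant - 1), 1 / 32 + 1e-9)

  set.seed(1)
  x <- rnorm(n)
  s3 <- make_stream(eda = x, rate = rate)
  f3 <- extract_features(preprocess_stream(s3), win)
  v <- preprocess_stream(s3)$channels$eda$data$value
  expect_lt(abs(f3$eda_time_rms^2 * length(v) - f3$eda_time_energy) /
              f3$eda_time_energy, 1e-6)
})

test_that("extraction is translation-invariant and deterministic", {
  g <- small_physio()
  pre <- preprocess_stream(g$stream)
  win <- segment_windows(pre)[1:5, ]
  f1 <- extract_features(pre, win)
  # shift every channel's timestamps by a constant
  sh <- g$stream
  for (nm in names(sh$channels))
    sh$channels[[nm]]$data$time <- sh$channels[[nm]]$data$time + 1000
  pre2 <- preprocess_stream(sh)
  win2 <- win
  win2$window_start <- win2$window_start + 1000
  win2$window_end <- win2$window_end + 1000
  f2 <- extract_features(pre2, win2)
  man <- attr(f1, "manifest")
  expect_lt(max(abs(as.matrix(f1[, man]) - as.matrix(f2[, man]))), 1e-6)
  expect_identical(f1, extract_features(pre, win))
})

test_that("manifest is canonical, ordered, and matches the matrix", {
  man <- physio_feature_manifest()
  expect_false(any(duplicated(man)))
  g <- small_physio()
  pre <- preprocess_stream(g$stream)
  f <- extract_features(pre, segment_windows(pre)[1:3, ])
  expect_identical(setdiff(colnames(f), c("window_start", "window_end")),
                   man)
  expect_true(all(is.finite(as.matrix(f[, man]))))
})

test_that("feature ranking orders by importance with canonical tie-break", {
  fit <- list(importance = c(b = 0.2, a = 0.5, c = 0.2),
              manifest = c("b", "a", "c"))
  r <- rank_features(fit, fit$manifest)
  expect_equal(r$feature, c("a", "b", "c"))
  # uniform importances -> canonical order preserved
  fit2 <- list(importance = c(x = 1, y = 1, z = 1) / 3,
               manifest = c("x", "y", "z"))
  expect_equal(rank_features(fit2, fit2$manifest)$feature, c("x", "y", "z"))
})

test_that("permutation importance ranks the informative feature first", {
  set.seed(41)
  n <- 160
  X <- data.frame(f1 = c(rnorm(n / 2, 0), rnorm(n / 2, 4)),
                  f2 = rnorm(n), f3 = rnorm(n))
  y <- rep(c("normal", "agitation"), each = n / 2)
  fit <- train_classifier(X, y, "mlp", seed = 2)
  expect_error(rank_features(fit), "permutation importance")
  r <- rank_features(fit, features = X, labels = y)
  expect_equal(r$feature[1], "f1")
  expect_gt(r$importance[1], max(r$importance[-1]))
})

test_that("a dominant-eda recording ranks an electrodermal feature on top", {
  cfg <- physio_sim_config(duration_s = 10800, n_episodes = 3,
                           episode_duration_range_s = c(120, 500),
                           episode_total_range_s = c(600, 900),
                           channel_gain = c(eda = 1.5, acc = 0.15,
                                            temp = 0.15),
                           seed = 31)
  tab <- participant_feature_table(list(stream = generate_physio(cfg)$stream,
                                        labels = generate_physio(cfg)$labels))
  tab <- tab[tab$label != "preagitation", ]
  up <- upsample(tab[, physio_feature_manifest()], tab$label, 1)
  fit <- train_classifier(up$features, up$labels, "extra_trees",
                          manifest = physio_feature_manifest(), seed = 1)
  top10 <- head(rank_features(fit)$feature, 10)
  expect_true(any(grepl("^eda", top10)))
})
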