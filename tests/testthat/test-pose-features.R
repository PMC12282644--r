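test_that("pose normalization centers, scales, and is invariant", {
  set.seed(19)
  f <- random_frame()
  n <- normalize_pose(f)
  expect_true(attr(n, "usable"))
  expect_equal(n$x1, 0)
  expect_equal(n$y1, 0)
  # normalized trunk length is exactly 1
  trunk <- sqrt((n$x1 - (n$x9 + n$x10) / 2)^2 + (n$y1 - (n$y9 + n$y10) / 2)^2)
  expect_equal(trunk, 1)
  # similarity transform (scale x2 about an arbitrary point + shift)
  f2 <- f
  for (j in 1:14) {
    f2[[paste0("x", j)]] <- 2 * (f[[paste0("x", j)]] - 50) + 300
    f2[[paste0("y", j)]] <- 2 * (f[[paste0("y", j)]] - 80) - 40
  }
  n2 <- normalize_pose(f2)
  for (j in 1:14) {
    expect_equal(n2[[paste0("x", j)]], n[[paste0("x", j)]])
    expect_equal(n2[[paste0("y", j)]], n[[paste0("y", j)]])
  }
  # missing root -> unusable
  f3 <- f; f3$c1 <- 0
  expect_false(attr(normalize_pose(f3), "usable"))
})

test_that("axis-aligned cases: 3-4-5 distance and 90-degree angle", {
  f <- random_frame()
  f$x1 <- 0; f$y1 <- 0
  f$x5 <- 3; f$y5 <- 4
  f$x6 <- 0; f$y6 <- -10         # image-up from the root
  v <- extract_pose_features(f, f)
  expect_equal(unname(v["eu_1_5"]), 5)
  expect_equal(unname(v["ang_1_6"]), 90)
  expect_true(all(v[paste0("eu_", 1:14)] == 0))  # identical frames
})

test_that("pose features match the brute-force oracle", {
  set.seed(23)
  for (i in 1:25) {
    prev <- random_frame(time = i - 1)
    curr <- random_frame(time = i)
    got <- extract_pose_features(prev, curr)
    want <- oracle_pose_features(prev, curr)
    expect_lt(max(abs(got[names(want)] - want)), 1e-9)
  }
  expect_error(extract_pose_features(random_frame("a"), random_frame("b")),
               "different persons")
})

test_that("zero-confidence keypoints yield missing features", {
  set.seed(29)
  conf <- runif(14, 0.5, 1); conf[7] <- 0
  curr <- random_frame(conf = conf)
  v <- extract_pose_features(random_frame(), curr)
  expect_true(is.na(v["eu_7"]))
  expect_true(is.na(v["eu_1_7"]))
  expect_true(is.na(v["por_7_1"]))
  expect_true(is.na(v["ang_1_7"]))
  expect_false(anyNA(v[c("eu_8", "eu_1_8", "ang_1_8")]))
})

test_that("vectorized per-frame matrix agrees with the pairwise path", {
  g <- small_pose()
  fm <- pose_feature_matrix(g$frames[1:30, ])
  man <- pose_feature_manifest()
  for (i in c(2, 10, 30)) {
    v <- extract_pose_features(g$frames[i - 1, ], g$frames[i, ])
    expect_lt(max(abs(as.numeric(fm[i, man]) - v)), 1e-9)
  }
})

test_that("correlation reduction drops duplicates and is idempotent", {
  set.seed(31)
  X <- matrix(rnorm(200 * 6), 200, 6)
  X[, 4] <- X[, 1]                      # exact duplicate
  X[, 5] <- X[, 2] + rnorm(200, 0, 0.05)  # highly correlated
  colnames(X) <- paste0("f", 1:6)
  keep <- reduce_features(X, 0.8)
  expect_false("f4" %in% keep)
  expect_false("f5" %in% keep)
  expect_true(all(c("f1", "f2", "f3", "f6") %in% keep))
  # after reduction no retained pair exceeds the threshold
  cm <- abs(cor(X[, keep]))
  diag(cm) <- 0
  expect_lt(max(cm), 0.8)
  # idempotence
  expect_equal(reduce_features(X[, keep], 0.8), keep)
  # near-orthogonal random columns all retained (verified first)
  set.seed(33)
  Y <- matrix(rnorm(500 * 8), 500, 8)
  colnames(Y) <- paste0("g", 1:8)
  cy <- abs(cor(Y)); diag(cy) <- 0
  stopifnot(max(cy) < 0.8)
  expect_equal(reduce_features(Y, 0.8), colnames(Y))
  # constant columns: retained once, duplicate constants dropped
  Z <- cbind(a = rnorm(50), b = rep(1, 50), c = rep(1, 50))
  expect_equal(reduce_features(Z, 0.8), c("a", "b"))
})

test_that("greedy reduction is maximal-prefix valid (brute force)", {
  set.seed(37)
  for (rep in 1:5) {
    X <- matrix(rnorm(120 * 10), 120, 10)
    X[, sample(10, 3)] <- X[, sample(10, 3)] +
      matrix(rnorm(120 * 3, 0, 0.1), 120, 3)
    colnames(X) <- sprintf("f%02d", 1:10)
    keep <- reduce_features(X, 0.8)
    cm <- abs(cor(X))
    # every dropped feature must correlate > 0.8 with an earlier retained
    for (j in setdiff(colnames(X), keep)) {
      earlier <- keep[match(keep, colnames(X)) < match(j, colnames(X))]
      expect_true(any(cm[j, earlier] > 0.8), info = j)
    }
    for (j in keep) {
      earlier <- setdiff(keep[match(keep, colnames(X)) <
                                match(j, colnames(X))], j)
      if (length(earlier)) expect_true(all(cm[j, earlier] <= 0.8))
    }
  }
})

test_that("sliding windows: counts, labels, and missing-frame handling", {
  g <- small_pose()
  fm <- pose_feature_matrix(g$frames)
  # 300 s at 30-s window, 1-s stride -> 271
  w <- build_windows(fm, g$labels, 30, 1, 15)
  expect_equal(length(w$starts), floor((300 - 30) / 1) + 1)
  expect_equal(dim(w$tensor)[2], 30 * 15)
  # T = 60 -> 31 windows; T = 30 -> 1; T < window -> none
  fm60 <- fm[1:(60 * 15), ]
  expect_equal(length(build_windows(fm60, g$labels, 30, 1, 15)$starts), 31L)
  fm30 <- fm[1:(30 * 15), ]
  expect_equal(length(build_windows(fm30, g$labels, 30, 1, 15)$starts), 1L)
  fm29 <- fm[1:(29 * 15), ]
  expect_equal(length(build_windows(fm29, g$labels, 30, 1, 15)$starts), 0L)
  # positive-window count equals the brute-force interval oracle
  ep <- g$labels[g$labels$label == "agitation", , drop = FALSE]
  oracle <- vapply(w$starts, function(s)
    overlap_seconds(s, s + 30, ep) >= 15, TRUE)
  expect_equal(w$labels == "agitation", unname(oracle))
  # windows with > 20% missing frames are dropped
  fm_bad <- fm
  fm_bad[1:150, -1] <- NA      # first 10 s of frames missing
  wb <- build_windows(fm_bad, g$labels, 30, 1, 15)
  expect_lt(length(wb$starts), length(w$starts))
  expect_false(anyNA(wb$tensor))
})
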