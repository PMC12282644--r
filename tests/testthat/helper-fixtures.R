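# Shared fixtures. Heavyweight objects are built once per test run and
# cached in this environment; acceptance tests at cohort scale reuse the
# same per-seed summaries.

.fix <- new.env(parent = emptyenv())

# small physio recording (2 hours, 2 episodes) for unit tests
small_physio <- function(seed = 2) {
  key <- paste0("sp", seed)
  if (is.null(.fix[[key]])) {
    cfg <- physio_sim_config(duration_s = 7200, n_episodes = 2,
                             episode_duration_range_s = c(120, 500),
                             episode_total_range_s = c(400, 700),
                             seed = seed)
    .fix[[key]] <- generate_physio(cfg)
  }
  .fix[[key]]
}

# small labeled wristband feature table
small_table <- function(seed = 2, merge_preagitation = FALSE) {
  key <- paste0("st", seed, merge_preagitation)
  if (is.null(.fix[[key]]))
    .fix[[key]] <- participant_feature_table(small_physio(seed),
                                             merge_preagitation)
  .fix[[key]]
}

# small pose stream (5 minutes, 1 episode)
small_pose <- function(seed = 4) {
  key <- paste0("pp", seed)
  if (is.null(.fix[[key]])) {
    cfg <- pose_sim_config(duration_s = 300, n_episodes = 1,
                           episode_duration_range_s = c(60, 90),
                           seed = seed)
    .fix[[key]] <- generate_pose(cfg)
  }
  .fix[[key]]
}

small_pose_windows <- function(seed = 4, stride_s = 2) {
  key <- paste0("pw", seed, stride_s)
  if (is.null(.fix[[key]])) {
    g <- small_pose(seed)
    fm <- pose_feature_matrix(g$frames)
    .fix[[key]] <- build_windows(fm, g$labels, 30, stride_s, 15)
  }
  .fix[[key]]
}

# Per-seed cohort summary at the default scale: labeled feature tables
# (binary + pre-agitation-merged views of the same features) plus truth
# labels; the raw streams are discarded to bound memory.
cohort_summary <- function(seed) {
  key <- paste0("cs", seed)
  if (is.null(.fix[[key]])) {
    co <- generate_cohort(10, seed = seed)
    tables <- list(); merged <- list(); truth <- list(); dominant <- c()
    for (p in co$participants) {
      pre <- preprocess_stream(p$physio$stream)
      win <- segment_windows(pre, 60, 60)
      fm <- extract_features(pre, win)
      tables[[p$id]] <- label_windows(fm, p$physio$labels)
      merged[[p$id]] <- label_windows(fm, p$physio$labels,
                                      preagitation = "merge")
      truth[[p$id]] <- p$physio$labels
      dominant[p$id] <- p$dominant
    }
    .fix[[key]] <- list(tables = tables, merged = merged, truth = truth,
                        dominant = dominant)
    rm(co); gc(verbose = FALSE)
  }
  .fix[[key]]
}

random_frame <- function(person = "p1", time = 0, conf = NULL) {
  f <- data.frame(time = time, person_id = person)
  xs <- runif(14, 0, 640); ys <- runif(14, 0, 480)
  cs <- if (is.null(conf)) runif(14, 0.5, 1) else conf
  for (j in 1:14) f[[paste0("x", j)]] <- xs[j]
  for (j in 1:14) f[[paste0("y", j)]] <- ys[j]
  for (j in 1:14) f[[paste0("c", j)]] <- cs[j]
  f
}

# independent brute-force recomputation of the geometric pose features
oracle_pose_features <- function(prev, curr) {
  gx <- function(f, j) f[[paste0("x", j)]]
  gy <- function(f, j) f[[paste0("y", j)]]
  trunk <- sqrt((gx(curr, 1) - (gx(curr, 9) + gx(curr, 10)) / 2)^2 +
                  (gy(curr, 1) - (gy(curr, 9) + gy(curr, 10)) / 2)^2)
  out <- c()
  for (k in 1:14)
    out[paste0("eu_", k)] <- sqrt((gx(curr, k) - gx(prev, k))^2 +
                                    (gy(curr, k) - gy(prev, k))^2)
  for (j in 3:14)
    out[paste0("eu_1_", j)] <- sqrt((gx(curr, j) - gx(curr, 1))^2 +
                                      (gy(curr, j) - gy(curr, 1))^2)
  for (i in 2:14)
    out[paste0("por_", i, "_1")] <-
      sqrt((gx(curr, i) - gx(curr, 1))^2 +
             (gy(curr, i) - gy(curr, 1))^2) / trunk
  for (j in 2:14) {
    a <- atan2(-(gy(curr, j) - gy(curr, 1)),
               gx(curr, j) - gx(curr, 1)) * 180 / pi
    out[paste0("ang_1_", j)] <- a %% 360
  }
  out
}

# miniature end-to-end pipeline configuration (scaled down for budget)
tiny_config <- function(seed = 1) {
  run_config(
    n_participants = 2L,
    physio = unclass(physio_sim_config(duration_s = 5400, n_episodes = 2,
                                       episode_duration_range_s = c(300, 720),
                                       episode_total_range_s = c(960, 1200))),
    pose = unclass(pose_sim_config(duration_s = 240, n_episodes = 1,
                                   episode_duration_range_s = c(60, 90))),
    epochs = 3L, frame_stride = 5L, seed = seed)
}

# brute-force interval overlap (seconds) between [s1,e1) and a table of
# intervals -- the independent oracle for window labeling
overlap_seconds <- function(s1, e1, intervals) {
  if (!nrow(intervals)) return(0)
  sum(pmax(0, pmin(e1, intervals$end) - pmax(s1, intervals$start)))
}

# brute-force event assembly oracle: run-length scan + merge
oracle_events <- function(dec, min_consecutive, merge_gap_s) {
  runs <- rle(as.logical(dec$decision))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ev <- data.frame(start = numeric(), end = numeric())
  for (k in seq_along(runs$values)) {
    if (runs$values[k] && runs$lengths[k] >= min_consecutive)
      ev <- rbind(ev, data.frame(start = dec$window_start[starts[k]],
                                 end = dec$window_end[ends[k]]))
  }
  if (nrow(ev) < 2L) return(ev)
  out <- ev[1L, ]
  for (k in 2:nrow(ev)) {
    if (ev$start[k] - out$end[nrow(out)] <= merge_gap_s)
      out$end[nrow(out)] <- ev$end[k]
    else out <- rbind(out, ev[k, ])
  }
  out
}
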