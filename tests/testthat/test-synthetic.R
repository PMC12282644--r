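test_that("physio generation is deterministic under the seed", {
  cfg <- physio_sim_config(duration_s = 1800, n_episodes = 1,
                           episode_duration_range_s = c(120, 300),
                           episode_total_range_s = c(120, 300), seed = 11)
  a <- generate_physio(cfg)
  b <- generate_physio(cfg)
  expect_identical(a$stream$channels, b$stream$channels)
  expect_identical(a$biomarkers, b$biomarkers)
  expect_identical(as.data.frame(a$labels), as.data.frame(b$labels))
})

test_that("null model: no episodes, minute-mean pulse near baseline", {
  cfg <- physio_sim_config(duration_s = 3600, n_episodes = 0, seed = 5)
  g <- generate_physio(cfg)
  expect_equal(nrow(g$labels), 0L)
  m <- mean(g$biomarkers$pulse_rate)
  # AR(1) minute means are correlated; allow a generous 3-SE-style band
  expect_lt(abs(m - 67.5), 3 * 12.4 / sqrt(6))
})

test_that("episode regime raises in-episode pulse by at least 15 bpm", {
  g <- small_physio()
  pulse <- g$stream$channels$pulse$data
  ag <- g$labels[g$labels$label == "agitation", ]
  inside <- vapply(pulse$time, function(t)
    any(t >= ag$start & t < ag$end), TRUE)
  expect_gt(mean(pulse$value[inside]) - mean(pulse$value[!inside]), 15)
})

test_that("every agitation episode carries a matching pre-agitation phase", {
  g <- small_physio()
  ag <- g$labels[g$labels$label == "agitation", ]
  pre <- g$labels[g$labels$label == "preagitation", ]
  expect_equal(nrow(pre), nrow(ag))
  for (i in seq_len(nrow(ag))) {
    j <- which(abs(pre$end - ag$start[i]) < 1e-9)
    expect_length(j, 1L)
    expect_equal(pre$end[j] - pre$start[j], 420)
  }
})

test_that("episode separation holds and collapses when labels are shifted", {
  sm <- small_table()
  dom <- sm$pulse_stat_mean   # pulse carries the full shift
  ag <- sm$label == "agitation"
  base <- sm$label == "normal"
  sep <- (mean(dom[ag]) - mean(dom[base])) / sd(dom[base])
  expect_gt(sep, 2)
  # shift labels +10 min: separation on the same signal must collapse
  g <- small_physio()
  shifted <- as.data.frame(g$labels)
  shifted$start <- shifted$start + 600
  shifted$end <- shifted$end + 600
  shifted <- shifted[shifted$end <= max(sm$window_end), ]
  lab2 <- label_windows(sm[, c("window_start", "window_end")],
                        episode_labels(shifted$participant_id,
                                       shifted$start, shifted$end,
                                       shifted$label, shifted$source))
  ag2 <- lab2$label == "agitation"
  if (any(ag2)) {
    sep2 <- (mean(dom[ag2]) - mean(dom[lab2$label == "normal"])) /
      sd(dom[lab2$label == "normal"])
    expect_lt(sep2, sep / 2)
  }
})

test_that("episodes that cannot fit raise a config error", {
  cfg <- physio_sim_config(duration_s = 1200, n_episodes = 6, seed = 1)
  expect_error(generate_physio(cfg), "config error")
})

test_that("pose generation: determinism, rigidity, kick excursions", {
  cfg <- pose_sim_config(duration_s = 60, n_episodes = 0, noise_sd_px = 0,
                         behaviors_normal = "idle", seed = 9)
  a <- generate_pose(cfg)
  b <- generate_pose(cfg)
  expect_identical(a$frames, b$frames)
  # idle with zero noise: rigid figure, inter-keypoint distances constant
  d27 <- sqrt((a$frames$x2 - a$frames$x7)^2 + (a$frames$y2 - a$frames$y7)^2)
  expect_lt(diff(range(d27)), 1e-9)

  kcfg <- pose_sim_config(duration_s = 120, n_episodes = 1,
                          episode_duration_range_s = c(40, 60),
                          behaviors_agitated = "kick",
                          behaviors_normal = "idle", seed = 10)
  g <- generate_pose(kcfg)
  ep <- g$labels
  tt <- g$frames$time
  inside <- tt >= ep$start[1] & tt < ep$end[1]
  hx <- (g$frames$x9 + g$frames$x10) / 2
  hy <- (g$frames$y9 + g$frames$y10) / 2
  foot <- pmax(sqrt((g$frames$x13 - hx)^2 + (g$frames$y13 - hy)^2),
               sqrt((g$frames$x14 - hx)^2 + (g$frames$y14 - hy)^2))
  expect_gt(max(foot[inside]), max(foot[!inside]))
  expect_gt(max(foot[inside]), 2 * median(foot[!inside]))
})

test_that("unknown behavior names are rejected", {
  expect_error(pose_sim_config(behaviors_agitated = c("pace", "somersault")),
               "unknown behavior")
})

test_that("cohorts are reproducible with rotating dominant channels", {
  a <- generate_cohort(3, physio_sim_config(duration_s = 3600,
                                            n_episodes = 1,
                                            episode_duration_range_s =
                                              c(120, 300),
                                            episode_total_range_s =
                                              c(120, 300)),
                       pose_sim_config(duration_s = 60, n_episodes = 0),
                       seed = 21)
  b <- generate_cohort(3, physio_sim_config(duration_s = 3600,
                                            n_episodes = 1,
                                            episode_duration_range_s =
                                              c(120, 300),
                                            episode_total_range_s =
                                              c(120, 300)),
                       pose_sim_config(duration_s = 60, n_episodes = 0),
                       seed = 21)
  ids <- vapply(a$participants, `[[`, "", "id")
  expect_equal(length(unique(ids)), 3L)
  expect_identical(a$participants[[2]]$physio$biomarkers,
                   b$participants[[2]]$physio$biomarkers)
  doms <- vapply(a$participants, `[[`, "", "dominant")
  expect_setequal(doms, c("eda", "acc", "temp"))
})
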