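test_that("physio stream CSV round-trips losslessly", {
  g <- small_physio()
  path <- withr::local_tempfile(fileext = ".csv")
  save_physio_csv(g$stream, path)
  back <- load_physio_csv(path, "p1")
  for (nm in names(g$stream$channels)) {
    a <- g$stream$channels[[nm]]$data
    b <- back$channels[[nm]]$data
    expect_equal(nrow(a), nrow(b), info = nm)
    expect_lt(max(abs(a$value - b$value)), 1e-9)
    expect_lt(max(abs(a$time - b$time)), 1e-9)
    expect_lt(abs(back$channels[[nm]]$rate - g$stream$channels[[nm]]$rate) /
                g$stream$channels[[nm]]$rate, 0.01)
  }
})

test_that("load_physio_csv rejects malformed input", {
  empty <- withr::local_tempfile(fileext = ".csv")
  file.create(empty)
  expect_error(load_physio_csv(empty), "format error")

  no_time <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2"), no_time)
  expect_error(load_physio_csv(no_time), "missing 'time'")

  non_mono <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,eda", "0,1", "2,1", "1,1"), non_mono)
  expect_error(load_physio_csv(non_mono), "non-monotonic.*row 3")

  ok <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,eda", "0.0,5", "0.25,5.1", "0.5,5.2"), ok)
  s <- load_physio_csv(ok)
  expect_equal(s$channels$eda$rate, 4)
  expect_equal(nrow(s$channels$eda$data), 3L)
})

test_that("episode label loading enforces the invariants", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(participant_id = "p1", start = 100, end = 200,
                       label = "agitation", source = "camera"),
            path, row.names = FALSE)
  labs <- load_labels(path)
  expect_s3_class(labs, "episode_labels")
  expect_equal(nrow(labs), 1L)

  expect_error(episode_labels("p1", 200, 100, "agitation", "camera"),
               "end must exceed start")
  expect_error(episode_labels("p1", 1, 2, "angry", "camera"),
               "unknown label")
  expect_error(
    episode_labels(c("p1", "p1"), c(0, 50), c(100, 150),
                   c("agitation", "agitation"), c("camera", "camera")),
    "overlapping")
  # different participants may overlap freely
  expect_silent(
    episode_labels(c("p1", "p2"), c(0, 50), c(100, 150),
                   c("agitation", "agitation"), c("camera", "camera")))
})

test_that("six episodes spanning 2 to 23 minutes load as labeled", {
  durs <- c(120, 300, 500, 800, 1100, 1380)
  starts <- cumsum(c(0, head(durs, -1) + 600))
  labs <- episode_labels(rep("p1", 6), starts, starts + durs,
                         rep("agitation", 6), rep("nurse_note", 6))
  d <- labs$end - labs$start
  expect_equal(length(d), 6L)
  expect_equal(min(d), 120)
  expect_equal(max(d), 1380)
  path <- withr::local_tempfile(fileext = ".csv")
  save_labels(labs, path)
  expect_equal(load_labels(path), labs)
})

test_that("window labeling follows the overlap rule and matches the oracle", {
  ep <- episode_labels("p1", 300, 600, "agitation", "camera")
  win <- data.frame(window_start = seq(0, 540, 60),
                    window_end = seq(60, 600, 60))
  lab <- label_windows(win, ep)
  # fully inside -> agitation; 20 s overlap < 30 s -> normal
  expect_equal(lab$label[lab$window_start == 300], "agitation")
  lab2 <- label_windows(data.frame(window_start = 260, window_end = 320),
                        ep)
  expect_equal(lab2$label, "normal")  # 20 s overlap < 30
  # oracle comparison over a misaligned episode
  ep2 <- episode_labels("p1", 133, 433, "agitation", "camera")
  lab3 <- label_windows(win, ep2)
  oracle <- vapply(seq_len(nrow(win)), function(i)
    overlap_seconds(win$window_start[i], win$window_end[i],
                    ep2) >= 30, TRUE)
  expect_equal(lab3$label == "agitation", oracle)
})

test_that("window labeling is order-independent and total", {
  set.seed(7)
  ep <- episode_labels(rep("p1", 3), c(100, 700, 1500),
                       c(400, 1000, 1700),
                       rep("agitation", 3), rep("camera", 3))
  win <- data.frame(window_start = seq(0, 1740, 60),
                    window_end = seq(60, 1800, 60))
  base <- label_windows(win, ep)
  for (i in 1:5) {
    shuffled <- ep[sample(nrow(ep)), ]
    class(shuffled) <- class(ep)
    expect_equal(label_windows(win, shuffled)$label, base$label)
  }
  expect_true(all(base$label %in% c("agitation", "preagitation", "normal")))
  expect_equal(nrow(base), nrow(win))   # every window labeled
  # empty episode table -> all normal
  expect_true(all(label_windows(win, episode_labels())$label == "normal"))
})

test_that("pre-agitation windows are held out by default, merged on demand", {
  ep <- episode_labels(c("p1", "p1"), c(600, 180), c(900, 600),
                       c("agitation", "preagitation"),
                       c("camera", "synthetic_truth"))
  win <- data.frame(window_start = seq(0, 840, 60),
                    window_end = seq(60, 900, 60))
  excl <- label_windows(win, ep)
  expect_true("preagitation" %in% excl$label)
  merg <- label_windows(win, ep, preagitation = "merge")
  expect_false("preagitation" %in% merg$label)
  expect_true(all(merg$label[excl$label == "preagitation"] == "agitation"))
  norm <- label_windows(win, ep, preagitation = "normal")
  expect_true(all(norm$label[excl$label == "preagitation"] == "normal"))
})

test_that("biomarker validation enforces ranges and wearing semantics", {
  g <- small_physio()
  expect_silent(validate_biomarkers(g$biomarkers))
  bad <- g$biomarkers
  bad$pulse_rate[3] <- 300
  expect_error(validate_biomarkers(bad), "pulse rate out of range")
  off <- g$biomarkers
  off$wearing[1] <- FALSE
  expect_error(validate_biomarkers(off), "not-worn")
  off$pulse_rate[1] <- NA
  off$temperature[1] <- NA
  expect_silent(validate_biomarkers(off))
})

test_that("pose frames round-trip through JSON-lines", {
  g <- small_pose()
  sub <- g$frames[1:20, ]
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_pose_jsonl(sub, path)
  back <- read_pose_jsonl(path)
  for (col in c("time", paste0("x", 1:14), paste0("y", 1:14),
                paste0("c", 1:14)))
    expect_lt(max(abs(back[[col]] - sub[[col]])), 1e-9)
  expect_equal(back$person_id, sub$person_id)
})
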