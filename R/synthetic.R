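#' @title Synthetic cohort generator
#' @description Generators that emulate the documented clinical signal
#'   regimes: agitation episodes 2-23 minutes long with a pre-agitation
#'   phase beginning about 7 minutes before onset; pulse near 67.5 (SD 12.4)
#'   bpm at baseline rising to ~100 (SD 11.6) bpm; activity counts 0-100 at
#'   baseline vs 50-140 when agitated; an elevated electrodermal tonic level
#'   and a small skin-temperature shift during episodes; and motor regimes
#'   (idle/walk vs pace/rock/kick/flail) for the pose channel.
#' @name synthetic
NULL

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Physiological simulation configuration
#'
#' Defaults encode the documented regimes: ~600 labeled minutes per
#' participant containing 6 episodes of 2-23 minutes totalling 20-32
#' minutes, a 420-second pre-agitation lead, baseline pulse 67.5 bpm
#' (SD 12.4) vs agitated 100 bpm (SD 11.6), activity counts 0-100 vs
#' 50-140, a +1.5 microsiemens tonic shift and a +0.4 C temperature shift.
#' Channel sampling rates follow wrist-device conventions: accelerometer
#' 32 Hz, electrodermal activity 4 Hz, temperature 1 Hz, pulse one sample
#' per 10-second estimation window.
#'
#' @param duration_s recording length (seconds).
#' @param n_episodes number of agitation episodes.
#' @param episode_duration_range_s per-episode duration bounds (seconds).
#' @param episode_total_range_s bounds on the summed episode time (seconds).
#' @param preagitation_lead_s pre-agitation phase length before each onset.
#' @param pulse_normal,pulse_agitated named `c(mean=, sd=)` pairs (bpm).
#' @param activity_counts_normal_range,activity_counts_agitated_range
#'   per-minute activity-count bounds.
#' @param eda_tonic_shift tonic electrodermal shift during episodes (uS).
#' @param temp_shift temperature shift during episodes (C).
#' @param channel_gain named multipliers on the episode shift of `eda`,
#'   `acc` and `temp` (used by [generate_cohort()] to rotate the dominant
#'   channel across participants).
#' @param baseline_eda resting tonic skin conductance level (uS).
#' @param baseline_temp resting peripheral temperature (C).
#' @param move_scale scale of the baseline ambulation burst process (g).
#' @param seed integer RNG seed.
#' @return list of class `physio_sim_config`.
#' @export
physio_sim_config <- function(duration_s = 36000,
                              n_episodes = 6,
                              episode_duration_range_s = c(120, 1380),
                              episode_total_range_s = c(1200, 1920),
                              preagitation_lead_s = 420,
                              pulse_normal = c(mean = 67.5, sd = 12.4),
                              pulse_agitated = c(mean = 100, sd = 11.6),
                              activity_counts_normal_range = c(0, 100),
                              activity_counts_agitated_range = c(50, 140),
                              eda_tonic_shift = 1.5,
                              temp_shift = 0.4,
                              channel_gain = c(eda = 1, acc = 1, temp = 1),
                              baseline_eda = 2,
                              baseline_temp = 33.5,
                              move_scale = 0.10,
                              seed = 1L) {
  cfg <- list(duration_s = duration_s, n_episodes = n_episodes,
              episode_duration_range_s = episode_duration_range_s,
              episode_total_range_s = episode_total_range_s,
              preagitation_lead_s = preagitation_lead_s,
              pulse_normal = pulse_normal, pulse_agitated = pulse_agitated,
              activity_counts_normal_range = activity_counts_normal_range,
              activity_counts_agitated_range = activity_counts_agitated_range,
              eda_tonic_shift = eda_tonic_shift, temp_shift = temp_shift,
              channel_gain = channel_gain, baseline_eda = baseline_eda,
              baseline_temp = baseline_temp, move_scale = move_scale,
              seed = as.integer(seed))
  class(cfg) <- "physio_sim_config"
  cfg
}

# Place n episodes inside [0, duration) leaving room for the pre-agitation
# lead plus a guard gap before each onset and after each offset.
schedule_episodes <- function(duration_s, n, dur_range, total_range,
                              lead_s, guard_s = 180) {
  if (n == 0L) return(data.frame(start = numeric(), end = numeric()))
  lo <- max(dur_range[1L] * n, total_range[1L])
  hi <- min(dur_range[2L] * n, total_range[2L])
  if (lo > hi) stop("config error: episode duration and total ranges conflict")
  total <- stats::runif(1, lo, hi)
  w <- stats::rgamma(n, shape = 2)
  dur <- dur_range[1L] + (total - n * dur_range[1L]) * w / sum(w)
  dur <- pmin(dur, dur_range[2L])
  slot <- lead_s + guard_s            # dead time reserved before each onset
  need <- sum(dur) + n * slot + guard_s
  if (need > duration_s)
    stop("config error: episodes and buffers do not fit within duration")
  slack <- duration_s - need
  g <- stats::rgamma(n + 1L, shape = 1)
  gaps <- slack * g / sum(g)
  starts <- numeric(n)
  t <- 0
  for (i in seq_len(n)) {
    t <- t + gaps[i] + slot
    starts[i] <- t
    t <- t + dur[i]
  }
  data.frame(start = starts, end = starts + dur)
}

# AR(1) series on a 1-second lattice with stationary marginal sd.
ar1_series <- function(n, phi, sd_marg) {
  innov_sd <- sd_marg * sqrt(1 - phi^2)
  x <- as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd), phi,
                                method = "recursive",
                                init = stats::rnorm(1, 0, sd_marg)))
  x
}

# Regime curve on the 1-second lattice: 0 at baseline, 1 during an episode.
# The pre-agitation phase ramps from 0 to 1 over its first `ramp_s` seconds
# and then holds near the agitated level until onset, matching the reported
# observation that physiology already sat in the agitated band during the
# pre-agitation phase.
regime_curve <- function(n_sec, episodes, lead_s, ramp_s = 120) {
  r <- numeric(n_sec)
  tt <- seq_len(n_sec) - 1
  for (i in seq_len(nrow(episodes))) {
    s <- episodes$start[i]; e <- episodes$end[i]
    r[tt >= s & tt < e] <- 1
    if (lead_s > 0) {
      ps <- s - lead_s
      in_ramp <- tt >= ps & tt < min(ps + ramp_s, s)
      r[in_ramp] <- pmax(r[in_ramp], (tt[in_ramp] - ps) / ramp_s)
      in_hold <- tt >= ps + ramp_s & tt < s
      r[in_hold] <- pmax(r[in_hold], 1)
    }
  }
  r
}

sample_at <- function(lattice, times) {
  idx <- pmin(length(lattice), pmax(1L, floor(times) + 1L))
  lattice[idx]
}

#' Generate a synthetic wristband recording
#'
#' Produces a raw multichannel stream, a minute-level digital-biomarker
#' table derived from it, and ground-truth agitation plus pre-agitation
#' labels. Baselines are smoothed AR(1) processes (coefficient 0.95 on a
#' 1-second lattice) so minute-level features carry realistic
#' autocorrelation; episode shifts enter through a regime curve that ramps
#' up over the first two minutes of the pre-agitation phase. Identical seeds
#' give identical output.
#'
#' @param config a [physio_sim_config()].
#' @param participant_id id recorded on all outputs.
#' @return list with `stream` ([physio_stream()]), `biomarkers`
#'   (minute-level data.frame) and `labels` ([episode_labels()]).
#' @export
generate_physio <- function(config, participant_id = "p1") {
  stopifnot(inherits(config, "physio_sim_config"))
  with_seed(config$seed, {
    n_sec <- ceiling(config$duration_s)
    ep <- schedule_episodes(config$duration_s, config$n_episodes,
                            config$episode_duration_range_s,
                            config$episode_total_range_s,
                            config$preagitation_lead_s)
    r <- regime_curve(n_sec, ep, config$preagitation_lead_s)
    gain <- config$channel_gain
    tt <- seq_len(n_sec) - 1

    # pulse (bpm): AR(1) baseline + regime shift; sd interpolates between
    # the documented baseline and agitated SDs.
    sd_t <- config$pulse_normal["sd"] +
      r * (config$pulse_agitated["sd"] - config$pulse_normal["sd"])
    pulse_lat <- config$pulse_normal["mean"] +
      r * (config$pulse_agitated["mean"] - config$pulse_normal["mean"]) +
      ar1_series(n_sec, 0.95, 1) * sd_t
    pulse_t <- seq(0, n_sec - 10, by = 10)
    pulse <- sample_at(pulse_lat, pulse_t)

    # electrodermal activity (uS): slow tonic wander + regime shift +
    # phasic bursts whose rate triples during episodes.
    tonic_lat <- config$baseline_eda + ar1_series(n_sec, 0.995, 0.25) +
      r * config$eda_tonic_shift * gain["eda"]
    burst_rate <- (4 / 60) * (1 + 2 * r)      # bursts per second
    burst <- stats::rbinom(n_sec, 1L, pmin(1, burst_rate))
    amp <- stats::runif(n_sec, 0.1, 0.4) * burst
    eda_t <- seq(0, n_sec - 0.25, by = 0.25)
    phasic <- numeric(length(eda_t))
    hits <- which(burst == 1L)
    for (h in hits) {                          # 4-second exponential decay
      i0 <- (h - 1L) * 4L + 1L
      idx <- i0:min(length(eda_t), i0 + 16L)
      phasic[idx] <- phasic[idx] + amp[h] * exp(-(seq_along(idx) - 1) / 6)
    }
    eda <- pmax(0.05, sample_at(tonic_lat, eda_t) + phasic)

    # skin temperature (C): very slow wander + small regime shift.
    temp_lat <- config$baseline_temp + ar1_series(n_sec, 0.999, 0.1) +
      r * config$temp_shift * gain["temp"]
    temp_t <- seq(0, n_sec - 1)
    temp <- sample_at(temp_lat, temp_t)

    # accelerometer (g): gravity on z plus an oscillatory movement whose
    # amplitude tracks the regime, plus jitter. Baseline movement is not
    # flat: a slow positive burst process emulates ordinary ambulation
    # (activity counts span 0-100 at baseline), so episode movement must
    # stand out against real background variability.
    acc_t <- seq(0, n_sec - 1 / 32, by = 1 / 32)
    move_base <- config$move_scale * pmax(0, ar1_series(n_sec, 0.98, 1))
    amp_mov <- 0.03 + sample_at(move_base, acc_t) +
      sample_at(r, acc_t) * 0.32 * gain["acc"]
    ph <- stats::runif(3, 0, 2 * pi)
    f_mov <- 1.8
    acc_x <- amp_mov * sin(2 * pi * f_mov * acc_t + ph[1]) +
      stats::rnorm(length(acc_t), 0, 0.02)
    acc_y <- amp_mov * sin(2 * pi * f_mov * acc_t + ph[2]) +
      stats::rnorm(length(acc_t), 0, 0.02)
    acc_z <- 1 + 0.5 * amp_mov * sin(2 * pi * 2 * f_mov * acc_t + ph[3]) +
      stats::rnorm(length(acc_t), 0, 0.02)

    stream <- physio_stream(participant_id, list(
      acc_x = list(rate = 32, data = data.frame(time = acc_t, value = acc_x)),
      acc_y = list(rate = 32, data = data.frame(time = acc_t, value = acc_y)),
      acc_z = list(rate = 32, data = data.frame(time = acc_t, value = acc_z)),
      eda   = list(rate = 4,  data = data.frame(time = eda_t, value = eda)),
      temp  = list(rate = 1,  data = data.frame(time = temp_t, value = temp)),
      pulse = list(rate = 0.1, data = data.frame(time = pulse_t, value = pulse))
    ))

    # minute-level digital biomarkers
    n_min <- floor(n_sec / 60)
    ms <- (seq_len(n_min) - 1) * 60
    r_min <- vapply(seq_len(n_min),
                    function(i) mean(r[((i - 1) * 60 + 1):(i * 60)]), 0)
    cn <- config$activity_counts_normal_range
    ca <- config$activity_counts_agitated_range
    counts_mu <- mean(cn) + r_min * (mean(ca) - mean(cn))
    counts <- round(pmax(cn[1L], pmin(ca[2L],
      counts_mu + stats::rnorm(n_min, 0, diff(cn) / 5))))
    min_mean <- function(x, t_x) {
      idx <- findInterval(t_x, ms)
      as.numeric(tapply(x, factor(idx, levels = seq_len(n_min)), mean))
    }
    min_sd <- function(x, t_x) {
      idx <- findInterval(t_x, ms)
      as.numeric(tapply(x, factor(idx, levels = seq_len(n_min)), stats::sd))
    }
    acc_mag <- sqrt(acc_x^2 + acc_y^2 + acc_z^2)
    biomarkers <- data.frame(
      participant_id = participant_id,
      minute_start = ms,
      pulse_rate = pmin(250, pmax(20, min_mean(pulse_lat[seq_len(n_min * 60)],
                                               seq(0, n_min * 60 - 1)))),
      pulse_rate_variability = pmax(5, 45 - 25 * r_min +
                                      stats::rnorm(n_min, 0, 4)),
      respiratory_rate = pmin(40, pmax(8, 14 + 6 * r_min +
                                         stats::rnorm(n_min, 0, 1.5))),
      activity_counts = counts,
      steps = round(counts * stats::runif(n_min, 0.5, 0.9)),
      acc_magnitude_sd = min_sd(acc_mag, acc_t),
      activity_class = ifelse(counts > 50, "moving", "stationary"),
      skin_conductance_level = min_mean(tonic_lat[seq_len(n_min * 60)],
                                        seq(0, n_min * 60 - 1)),
      wearing = TRUE,
      temperature = min_mean(temp, temp_t),
      stringsAsFactors = FALSE
    )

    labels <- if (nrow(ep)) {
      episode_labels(
        participant_id = rep(participant_id, 2L * nrow(ep)),
        start = c(ep$start, ep$start - config$preagitation_lead_s),
        end = c(ep$end, ep$start),
        label = rep(c("agitation", "preagitation"), each = nrow(ep)),
        source = "synthetic_truth")
    } else episode_labels()

    list(stream = stream, biomarkers = biomarkers, labels = labels)
  })
}

#' Pose simulation configuration
#'
#' Defaults: a 15-minute keypoint stream at 15 frames/second containing two
#' 1-3 minute agitation episodes; normal behavior alternates idle and
#' walking, episodes alternate among pacing, rocking, kicking and flailing.
#'
#' @param duration_s stream length (seconds).
#' @param fps frames per second; `fps * duration_s` frames are emitted.
#' @param n_episodes number of agitation episodes.
#' @param episode_duration_range_s per-episode duration bounds (seconds).
#' @param behaviors_normal subset of `c("idle", "walk")`.
#' @param behaviors_agitated subset of `c("pace", "rock", "kick", "flail")`.
#' @param noise_sd_px Gaussian keypoint jitter (pixels).
#' @param seed integer RNG seed.
#' @return list of class `pose_sim_config`.
#' @export
pose_sim_config <- function(duration_s = 900, fps = 15, n_episodes = 2,
                            episode_duration_range_s = c(60, 180),
                            behaviors_normal = c("idle", "walk"),
                            behaviors_agitated = c("pace", "rock", "kick",
                                                   "flail"),
                            noise_sd_px = 2, seed = 1L) {
  known_n <- c("idle", "walk"); known_a <- c("pace", "rock", "kick", "flail")
  if (length(setdiff(behaviors_normal, known_n)))
    stop("config error: unknown behavior '",
         setdiff(behaviors_normal, known_n)[1L], "'")
  if (length(setdiff(behaviors_agitated, known_a)))
    stop("config error: unknown behavior '",
         setdiff(behaviors_agitated, known_a)[1L], "'")
  cfg <- list(duration_s = duration_s, fps = fps, n_episodes = n_episodes,
              episode_duration_range_s = episode_duration_range_s,
              behaviors_normal = behaviors_normal,
              behaviors_agitated = behaviors_agitated,
              noise_sd_px = noise_sd_px, seed = as.integer(seed))
  class(cfg) <- "pose_sim_config"
  cfg
}

# Canonical 14-keypoint layout (pixels, y grows downward):
# 1 neck/torso root, 2 head, 3/4 shoulders, 5/6 elbows, 7/8 wrists,
# 9/10 hips, 11/12 knees, 13/14 ankles.
.base_skeleton <- function(scale = 100) {
  m <- rbind(
    c(0, 0),        # 1 neck (root)
    c(0, -0.35),    # 2 head
    c(-0.22, 0.05), # 3 L shoulder
    c(0.22, 0.05),  # 4 R shoulder
    c(-0.30, 0.45), # 5 L elbow
    c(0.30, 0.45),  # 6 R elbow
    c(-0.32, 0.85), # 7 L wrist
    c(0.32, 0.85),  # 8 R wrist
    c(-0.15, 0.95), # 9 L hip
    c(0.15, 0.95),  # 10 R hip
    c(-0.17, 1.45), # 11 L knee
    c(0.17, 1.45),  # 12 R knee
    c(-0.18, 1.95), # 13 L ankle
    c(0.18, 1.95)   # 14 R ankle
  )
  m * scale
}

#' Generate a synthetic skeletal keypoint stream
#'
#' Emits a 14-keypoint articulated figure per frame. Idle is low-amplitude
#' jitter; walking adds sinusoidal limb phase and root translation; pacing
#' is walking with direction reversals every 2-4 seconds; rocking
#' oscillates the torso angle at 0.8-1.5 Hz; kicking produces periodic foot
#' excursions that at least double the idle foot-to-torso distance;
#' flailing draws high-variance arm angles. Keypoint confidences are
#' Uniform(0.5, 1). Deterministic under the seed.
#'
#' @param config a [pose_sim_config()].
#' @param participant_id person id stamped on each frame.
#' @return list with `frames` (wide data.frame: `time`, `person_id`,
#'   `x1..x14`, `y1..y14`, `c1..c14`) and `labels` ([episode_labels()]).
#' @export
generate_pose <- function(config, participant_id = "p1") {
  stopifnot(inherits(config, "pose_sim_config"))
  with_seed(config$seed, {
    n_frames <- round(config$fps * config$duration_s)
    t_f <- (seq_len(n_frames) - 1) / config$fps
    ep <- schedule_episodes(config$duration_s, config$n_episodes,
                            config$episode_duration_range_s,
                            c(config$episode_duration_range_s[1L] *
                                max(1, config$n_episodes),
                              config$episode_duration_range_s[2L] *
                                max(1, config$n_episodes)),
                            lead_s = 0, guard_s = 30)
    in_ep <- rep(FALSE, n_frames)
    for (i in seq_len(nrow(ep)))
      in_ep[t_f >= ep$start[i] & t_f < ep$end[i]] <- TRUE

    # behavior segmentation: 5-15 s segments, behavior drawn from the
    # normal or agitated menu according to the episode schedule
    beh <- character(n_frames)
    i <- 1L
    while (i <= n_frames) {
      seg_s <- stats::runif(1, 5, 15)
      j <- min(n_frames, i + round(seg_s * config$fps) - 1L)
      menu <- if (in_ep[i]) config$behaviors_agitated else
        config$behaviors_normal
      beh[i:j] <- sample(menu, 1L)
      # do not let a segment straddle an episode boundary
      flip <- which(in_ep[i:j] != in_ep[i])
      if (length(flip)) {
        j2 <- i + flip[1L] - 2L
        beh[(j2 + 1L):j] <- ""
        j <- j2
      }
      i <- j + 1L
    }

    base <- .base_skeleton()
    X <- matrix(0, n_frames, 14L); Y <- matrix(0, n_frames, 14L)
    root <- c(320, 120)
    vx <- 0; dir <- 1
    next_flip <- stats::runif(1, 2, 4)
    rock_f <- stats::runif(1, 0.8, 1.5)
    kick_side <- sample(c(13L, 14L), 1L)
    for (k in seq_len(n_frames)) {
      tme <- t_f[k]
      b <- beh[k]
      pts <- base
      phase <- 2 * pi * 1.0 * tme
      if (b %in% c("walk", "pace")) {
        if (b == "pace" && tme >= next_flip) {
          dir <- -dir
          next_flip <- tme + stats::runif(1, 2, 4)
        }
        vx <- if (b == "walk") 40 else 60 * dir
        root[1L] <- root[1L] + vx / config$fps
        if (root[1L] > 600) { root[1L] <- 600; dir <- -1 }
        if (root[1L] < 40)  { root[1L] <- 40;  dir <- 1 }
        sw <- sin(phase)
        pts[c(13L, 11L), 1L] <- pts[c(13L, 11L), 1L] + c(18, 9) * sw
        pts[c(14L, 12L), 1L] <- pts[c(14L, 12L), 1L] - c(18, 9) * sw
        pts[c(7L, 5L), 1L] <- pts[c(7L, 5L), 1L] - c(12, 6) * sw
        pts[c(8L, 6L), 1L] <- pts[c(8L, 6L), 1L] + c(12, 6) * sw
      } else if (b == "rock") {
        th <- 0.35 * sin(2 * pi * rock_f * tme)
        hip <- colMeans(pts[9:10, ])
        upper <- c(1:8)
        rel <- sweep(pts[upper, , drop = FALSE], 2, hip)
        rot <- cbind(rel[, 1L] * cos(th) - rel[, 2L] * sin(th),
                     rel[, 1L] * sin(th) + rel[, 2L] * cos(th))
        pts[upper, ] <- sweep(rot, 2, hip, "+")
      } else if (b == "kick") {
        # leg extends radially away from the hip midpoint, at least
        # doubling the idle foot-to-torso distance at full extension
        ext <- pmax(0, sin(2 * pi * 1.2 * tme))
        leg <- if (kick_side == 13L) c(11L, 13L) else c(12L, 14L)
        hip <- colMeans(pts[9:10, ])
        dir_a <- pts[leg[2L], ] - hip
        dir_a <- dir_a / sqrt(sum(dir_a^2))
        pts[leg[2L], ] <- pts[leg[2L], ] + ext * 150 * dir_a
        pts[leg[1L], ] <- pts[leg[1L], ] + ext * 65 * dir_a
      } else if (b == "flail") {
        for (side in c(-1, 1)) {
          th <- stats::runif(1, 0, 2 * pi)
          wr <- if (side < 0) 7L else 8L
          el <- if (side < 0) 5L else 6L
          sh <- if (side < 0) 3L else 4L
          pts[el, ] <- pts[sh, ] + 45 * c(cos(th), sin(th))
          th2 <- th + stats::runif(1, -1, 1)
          pts[wr, ] <- pts[el, ] + 45 * c(cos(th2), sin(th2))
        }
      }
      pts <- sweep(pts, 2, root, "+")
      if (config$noise_sd_px > 0)
        pts <- pts + matrix(stats::rnorm(28L, 0, config$noise_sd_px), 14L, 2L)
      X[k, ] <- pts[, 1L]; Y[k, ] <- pts[, 2L]
    }
    conf <- matrix(stats::runif(n_frames * 14L, 0.5, 1), n_frames, 14L)
    frames <- data.frame(time = t_f, person_id = participant_id)
    for (j in seq_len(14L)) frames[[paste0("x", j)]] <- X[, j]
    for (j in seq_len(14L)) frames[[paste0("y", j)]] <- Y[, j]
    for (j in seq_len(14L)) frames[[paste0("c", j)]] <- conf[, j]
    attr(frames, "fps") <- config$fps
    labels <- if (nrow(ep)) {
      episode_labels(participant_id = rep(participant_id, nrow(ep)),
                     start = ep$start, end = ep$end,
                     label = "agitation", source = "synthetic_truth")
    } else episode_labels()
    list(frames = frames, labels = labels, behaviors = beh)
  })
}

#' Generate a multimodal synthetic cohort
#'
#' Derives per-participant seeds deterministically from the master seed and
#' jitters participant-level parameters: baseline pulse mean within +/- 8
#' bpm, and the dominant agitated channel rotating among electrodermal
#' activity, accelerometry and temperature (the dominant channel's episode
#' shift is amplified, the others attenuated) to mirror the documented
#' inter-individual variability. The labeled recording length is the
#' template's (about 600 minutes per participant, the documented labeled
#' span) even though devices were worn for 24-72 hours: only the observed,
#' labeled span enters the analysis.
#'
#' @param n_participants cohort size (default 10).
#' @param physio_template a [physio_sim_config()] template.
#' @param pose_template a [pose_sim_config()] template.
#' @param seed master seed.
#' @return list of class `cohort`: per participant a list with `id`,
#'   `dominant`, `physio` (stream/biomarkers/labels) and `pose`
#'   (frames/labels).
#' @export
generate_cohort <- function(n_participants = 10,
                            physio_template = physio_sim_config(),
                            pose_template = pose_sim_config(),
                            seed = 1L) {
  stopifnot(n_participants >= 1)
  doms <- c("eda", "acc", "temp")
  cohort <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    pseed <- (as.integer(seed) * 7919L + i * 104729L) %% 2147483399L
    id <- sprintf("p%02d", i)
    dom <- doms[(i - 1L) %% 3L + 1L]
    # participant-level heterogeneity: baseline pulse within +/- 8 bpm,
    # plus the wide between-person spread of resting skin conductance,
    # peripheral temperature and ordinary mobility that makes a pooled
    # model genuinely harder than personalized ones
    jit <- with_seed(pseed, list(pulse = stats::runif(1, -8, 8),
                                 eda0 = stats::runif(1, 1, 6),
                                 temp0 = stats::runif(1, 32.5, 34.5),
                                 move = stats::runif(1, 0.05, 0.18)))
    gain <- c(eda = 0.15, acc = 0.15, temp = 0.15)
    gain[dom] <- 1.5
    pc <- physio_template
    pc$seed <- pseed
    pc$pulse_normal["mean"] <- physio_template$pulse_normal["mean"] + jit$pulse
    pc$pulse_agitated["mean"] <- physio_template$pulse_agitated["mean"] +
      jit$pulse
    pc$channel_gain <- gain
    pc$baseline_eda <- jit$eda0
    pc$baseline_temp <- jit$temp0
    pc$move_scale <- jit$move
    qc <- pose_template
    qc$seed <- (pseed + 17L) %% 2147483399L
    cohort[[i]] <- list(id = id, dominant = dom, seed = pseed,
                        physio = generate_physio(pc, id),
                        pose = generate_pose(qc, id))
  }
  structure(list(participants = cohort, seed = as.integer(seed)),
            class = "cohort")
}

#' Write a cohort bundle to disk
#'
#' One directory per participant holding the raw stream, biomarkers,
#' labels, pose frames (JSON-lines) and pose labels; a top-level
#' `manifest.json` records ids, seeds and dominant channels.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = cohort$seed, participants = list())
  for (p in cohort$participants) {
    pd <- file.path(dir, p$id)
    dir.create(pd, showWarnings = FALSE)
    save_physio_csv(p$physio$stream, file.path(pd, "stream.csv"))
    utils::write.csv(p$physio$biomarkers, file.path(pd, "biomarkers.csv"),
                     row.names = FALSE)
    save_labels(p$physio$labels, file.path(pd, "labels.csv"))
    write_pose_jsonl(p$pose$frames, file.path(pd, "pose.jsonl"))
    save_labels(p$pose$labels, file.path(pd, "pose_labels.csv"))
    manifest$participants[[p$id]] <-
      list(id = p$id, seed = p$seed, dominant = p$dominant)
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Write pose frames as JSON-lines (OpenPose-style subset)
#'
#' One object per line: `{"timestamp": t, "person_id": id,
#' "keypoints": [[x, y, c] x 14]}`.
#'
#' @param frames wide pose data.frame as produced by [generate_pose()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pose_jsonl <- function(frames, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(frames))) {
    kp <- lapply(seq_len(14L), function(j)
      c(frames[[paste0("x", j)]][i], frames[[paste0("y", j)]][i],
        frames[[paste0("c", j)]][i]))
    writeLines(jsonlite::toJSON(list(timestamp = frames$time[i],
                                     person_id = frames$person_id[i],
                                     keypoints = kp),
                                auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Read pose frames from JSON-lines
#' @param path input path written by [write_pose_jsonl()] or an OpenPose
#'   export restricted to the same keys.
#' @return wide pose data.frame (`time`, `person_id`, `x1..x14`, `y1..y14`,
#'   `c1..c14`).
#' @export
read_pose_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- length(lines)
  out <- data.frame(time = numeric(n), person_id = character(n),
                    stringsAsFactors = FALSE)
  mats <- replicate(3L, matrix(NA_real_, n, 14L), simplify = FALSE)
  for (i in seq_len(n)) {
    o <- jsonlite::fromJSON(lines[i])
    out$time[i] <- o$timestamp
    out$person_id[i] <- o$person_id
    kp <- o$keypoints
    if (is.list(kp)) kp <- do.call(rbind, kp)
    if (nrow(kp) != 14L) stop("format error: expected 14 keypoints, line ", i)
    for (d in 1:3) mats[[d]][i, ] <- kp[, d]
  }
  for (j in seq_len(14L)) out[[paste0("x", j)]] <- mats[[1L]][, j]
  for (j in seq_len(14L)) out[[paste0("y", j)]] <- mats[[2L]][, j]
  for (j in seq_len(14L)) out[[paste0("c", j)]] <- mats[[3L]][, j]
  out
}
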