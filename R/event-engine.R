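#' Assemble window decisions into detection events
#'
#' A run of at least `min_consecutive` positive windows opens an event;
#' events whose gap is at most `merge_gap_s` are merged. Event onset is
#' the start of the first positive window of the run, offset the end of
#' the last.
#'
#' @param decisions data.frame, time-ordered, with `window_start`,
#'   `window_end`, `probability` and logical/0-1 `decision`.
#' @param min_consecutive positives needed to open an event (default 2).
#' @param merge_gap_s maximum gap merged into one event (default 60).
#' @param participant_id,channel event metadata (`channel` one of
#'   `"wristband"`, `"video"`, `"fused"`).
#' @return data.frame of class `detection_events`: `participant_id`,
#'   `channel`, `onset`, `offset`, `n_windows`, `max_probability`,
#'   `review_status` (`"pending"`).
#' @export
assemble_episodes <- function(decisions, min_consecutive = 2L,
                              merge_gap_s = 60, participant_id = "unknown",
                              channel = "wristband") {
  stopifnot(channel %in% c("wristband", "video", "fused"))
  if (nrow(decisions) > 1L &&
      any(diff(decisions$window_start) < 0))
    stop("contract error: decisions must be time-ordered")
  pos <- as.logical(decisions$decision)
  ev <- list()
  i <- 1L
  n <- nrow(decisions)
  while (i <= n) {
    if (!pos[i]) { i <- i + 1L; next }
    j <- i
    while (j < n && pos[j + 1L]) j <- j + 1L
    if (j - i + 1L >= min_consecutive)
      ev[[length(ev) + 1L]] <-
        c(start = decisions$window_start[i], end = decisions$window_end[j],
          n = j - i + 1L,
          p = max(decisions$probability[i:j]))
    i <- j + 1L
  }
  if (!length(ev))
    return(structure(data.frame(participant_id = character(),
                                channel = character(), onset = numeric(),
                                offset = numeric(), n_windows = integer(),
                                max_probability = numeric(),
                                review_status = character()),
                     class = c("detection_events", "data.frame")))
  m <- do.call(rbind, ev)
  # merge events separated by <= merge_gap_s
  keep <- list(m[1L, ])
  for (k in seq_len(nrow(m))[-1L]) {
    last <- keep[[length(keep)]]
    if (m[k, "start"] - last["end"] <= merge_gap_s) {
      last["end"] <- m[k, "end"]
      last["n"] <- last["n"] + m[k, "n"]
      last["p"] <- max(last["p"], m[k, "p"])
      keep[[length(keep)]] <- last
    } else keep[[length(keep) + 1L]] <- m[k, ]
  }
  m <- do.call(rbind, keep)
  structure(data.frame(participant_id = participant_id, channel = channel,
                       onset = m[, "start"], offset = m[, "end"],
                       n_windows = as.integer(m[, "n"]),
                       max_probability = m[, "p"],
                       review_status = "pending",
                       stringsAsFactors = FALSE),
            class = c("detection_events", "data.frame"))
}

#' Attach pre/post context buffers to events
#'
#' Adds the 5-minute (default) context buffer on each side, clipped to the
#' stream bounds with the clipping recorded.
#'
#' @param events a `detection_events` data.frame.
#' @param stream_start,stream_end bounds of the underlying recording.
#' @param buffer_pre_s,buffer_post_s buffer lengths in seconds
#'   (default 300).
#' @return `events` with `buffered_start`, `buffered_end`, `clipped`
#'   columns.
#' @export
attach_buffers <- function(events, stream_start, stream_end,
                           buffer_pre_s = 300, buffer_post_s = 300) {
  bs <- events$onset - buffer_pre_s
  be <- events$offset + buffer_post_s
  events$clipped <- bs < stream_start | be > stream_end
  events$buffered_start <- pmax(stream_start, bs)
  events$buffered_end <- pmin(stream_end, be)
  events
}

#' Lead times of detections against ground truth
#'
#' Each ground-truth agitation episode is matched to the earliest
#' detection event whose buffered interval intersects
#' `[onset - match_window_s, end)`; the lead time is the truth onset minus
#' the first-alert time (the matched event's onset), positive when the
#' alert preceded the episode. Unmatched episodes are recorded as misses.
#'
#' @param events buffered `detection_events` (see [attach_buffers()]).
#' @param truth an [episode_labels()] table; only `agitation` rows are
#'   matched.
#' @param match_window_s how far before the truth onset an event may
#'   reach (default 900).
#' @return data.frame: `truth_start`, `truth_end`, `matched`,
#'   `alert_time`, `lead_s` (`NA` for misses).
#' @export
compute_lead_times <- function(events, truth, match_window_s = 900) {
  tr <- truth[truth$label == "agitation", , drop = FALSE]
  out <- data.frame(truth_start = tr$start, truth_end = tr$end,
                    matched = FALSE, alert_time = NA_real_,
                    lead_s = NA_real_)
  if (!nrow(events)) return(out)
  bs <- if ("buffered_start" %in% names(events)) events$buffered_start
        else events$onset
  be <- if ("buffered_end" %in% names(events)) events$buffered_end
        else events$offset
  for (i in seq_len(nrow(out))) {
    lo <- out$truth_start[i] - match_window_s
    hi <- out$truth_end[i]
    hit <- which(bs < hi & be > lo)
    if (length(hit)) {
      first <- hit[which.min(events$onset[hit])]
      out$matched[i] <- TRUE
      out$alert_time[i] <- events$onset[first]
      out$lead_s[i] <- out$truth_start[i] - events$onset[first]
    }
  }
  out
}

#' Create an append-only alert log
#' @return environment-backed alert log of class `alert_log`.
#' @export
alert_log <- function() {
  structure(new.env(parent = emptyenv()), class = "alert_log")
}

#' Emit an alert for a detection event
#'
#' Appends one alert record per event id; re-emitting the same id is
#' ignored with a warning (idempotence).
#'
#' @param event one-row `detection_events` data.frame.
#' @param log an [alert_log()].
#' @param event_id unique id; defaults to
#'   `participant:channel:onset`.
#' @return the alert record (list), invisibly `NULL` when duplicated.
#' @export
emit_alert <- function(event, log,
                       event_id = paste(event$participant_id,
                                        event$channel, event$onset,
                                        sep = ":")) {
  if (!is.null(log[[event_id]])) {
    warning("duplicate alert for event ", event_id, "; ignored")
    return(invisible(NULL))
  }
  rec <- list(event_id = event_id, time = event$onset,
              participant_id = event$participant_id,
              channel = event$channel,
              max_probability = event$max_probability)
  assign(event_id, rec, envir = log)
  rec
}

#' Read back the alert log in time order
#' @param log an [alert_log()].
#' @return data.frame of alert records.
#' @export
alert_records <- function(log) {
  recs <- lapply(ls(log), function(id) as.data.frame(log[[id]]))
  if (!length(recs))
    return(data.frame(event_id = character(), time = numeric()))
  out <- do.call(rbind, recs)
  out[order(out$time), , drop = FALSE]
}

#' Create a versioned training store
#' @return list of class `training_store` with `version = 0` and an empty
#'   window table.
#' @export
training_store <- function() {
  structure(list(version = 0L,
                 windows = data.frame(window_start = numeric(),
                                      window_end = numeric(),
                                      label = character(),
                                      event_id = character()),
                 reviewed = character()),
            class = "training_store")
}

#' Incorporate a reviewed event into the training store
#'
#' Confirmed events append their covered windows with agitation labels;
#' rejected events append them as normal. Each review bumps the store
#' version; reviewing the same event twice is a contract error.
#' Retraining is a separate, explicit call.
#'
#' @param store a [training_store()].
#' @param event one-row buffered `detection_events` data.frame.
#' @param decision `"confirmed"` or `"rejected"`.
#' @param windows data.frame of the event's covered windows
#'   (`window_start`, `window_end`).
#' @param event_id unique event id (default as in [emit_alert()]).
#' @return the updated store.
#' @export
incorporate_confirmed <- function(store, event,
                                  decision = c("confirmed", "rejected"),
                                  windows,
                                  event_id = paste(event$participant_id,
                                                   event$channel,
                                                   event$onset, sep = ":")) {
  decision <- match.arg(decision)
  if (event_id %in% store$reviewed)
    stop("contract error: event ", event_id, " already reviewed")
  lab <- if (decision == "confirmed") "agitation" else "normal"
  add <- data.frame(window_start = windows$window_start,
                    window_end = windows$window_end,
                    label = lab, event_id = event_id,
                    stringsAsFactors = FALSE)
  store$windows <- rbind(store$windows, add)
  store$reviewed <- c(store$reviewed, event_id)
  store$version <- store$version + 1L
  store
}

#' Fuse per-channel detection events
#'
#' Simple OR-fusion: the union of wristband and video events, with
#' overlapping intervals merged into one fused event.
#'
#' @param ... `detection_events` data.frames.
#' @return merged `detection_events` with `channel = "fused"`.
#' @export
fuse_events <- function(...) {
  evs <- do.call(rbind, lapply(list(...), function(e)
    e[, c("participant_id", "channel", "onset", "offset", "n_windows",
          "max_probability", "review_status")]))
  if (!nrow(evs)) { evs$channel <- character(); return(evs) }
  evs <- evs[order(evs$onset), , drop = FALSE]
  keep <- list(evs[1L, ])
  for (i in seq_len(nrow(evs))[-1L]) {
    last <- keep[[length(keep)]]
    if (evs$onset[i] <= last$offset) {
      last$offset <- max(last$offset, evs$offset[i])
      last$n_windows <- last$n_windows + evs$n_windows[i]
      last$max_probability <- max(last$max_probability,
                                  evs$max_probability[i])
      keep[[length(keep)]] <- last
    } else keep[[length(keep) + 1L]] <- evs[i, ]
  }
  out <- do.call(rbind, keep)
  out$channel <- "fused"
  rownames(out) <- NULL
  structure(out, class = c("detection_events", "data.frame"))
}
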