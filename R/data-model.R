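#' Construct a raw physiological stream
#'
#' A `physio_stream` bundles the multichannel wrist-worn recording of one
#' participant. Each channel carries its own sampling rate and an ordered
#' series of (time, value) samples. Expected channels and units:
#' `acc_x`/`acc_y`/`acc_z` in g, `eda` in microsiemens, `temp` in degrees
#' Celsius, `pulse` in beats per minute. Derived channels (`acc_mag`,
#' `eda_tonic`, `eda_phasic`) are added by [preprocess_stream()] and
#' [decompose_eda()].
#'
#' @param participant_id character scalar.
#' @param channels named list; each element a list with `rate` (Hz) and
#'   `data` (data.frame with numeric `time` in seconds since epoch and
#'   `value`).
#' @return object of class `physio_stream`.
#' @export
physio_stream <- function(participant_id, channels) {
  stopifnot(is.character(participant_id), length(participant_id) == 1L)
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    d <- ch$data
    if (!is.data.frame(d) || !all(c("time", "value") %in% names(d)))
      stop("channel '", nm, "': data must have time and value columns")
    if (anyNA(d$time) || anyNA(d$value))
      stop("channel '", nm, "': NA not allowed after loading")
    if (nrow(d) > 1L && any(diff(d$time) <= 0))
      stop("channel '", nm, "': timestamps must be strictly increasing (row ",
           which(diff(d$time) <= 0)[1L] + 1L, ")")
    if (!is.numeric(ch$rate) || ch$rate <= 0)
      stop("channel '", nm, "': sampling rate must be positive")
  }
  structure(list(participant_id = participant_id, channels = channels),
            class = "physio_stream")
}

#' @export
print.physio_stream <- function(x, ...) {
  cat("<physio_stream> participant", x$participant_id, "\n")
  for (nm in names(x$channels)) {
    ch <- x$channels[[nm]]
    cat(sprintf("  %-10s %8.3f Hz  %d samples\n", nm, ch$rate, nrow(ch$data)))
  }
  invisible(x)
}

#' Load a raw physiological stream from CSV
#'
#' Expects a header with a `time` column (seconds since epoch) plus one
#' column per channel. Each channel is stored at the rate implied by the
#' median inter-sample gap of its non-missing rows; rows with unparseable
#' values in a channel are dropped for that channel and counted.
#'
#' @param path CSV file path.
#' @param participant_id participant identifier recorded on the stream.
#' @return a [physio_stream()]; attribute `dropped` holds per-channel counts
#'   of discarded rows.
#' @export
load_physio_csv <- function(path, participant_id = "unknown") {
  if (!file.exists(path) || file.size(path) == 0L)
    stop("format error: empty or missing file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"time" %in% names(df))
    stop("format error: missing 'time' column in ", path)
  tcol <- suppressWarnings(as.numeric(df$time))
  if (anyNA(tcol))
    stop("format error: unparseable timestamps in ", path)
  if (length(tcol) > 1L && any(diff(tcol) <= 0))
    stop("data error: non-monotonic timestamps at row ",
         which(diff(tcol) <= 0)[1L] + 1L)
  chans <- setdiff(names(df), "time")
  if (length(chans) == 0L) stop("format error: no channel columns in ", path)
  dropped <- integer(0)
  out <- list()
  for (nm in chans) {
    v <- suppressWarnings(as.numeric(df[[nm]]))
    ok <- !is.na(v)
    dropped[nm] <- sum(!ok)
    tt <- tcol[ok]
    if (length(tt) < 2L) {
      rate <- 1
    } else {
      rate <- 1 / stats::median(diff(tt))
    }
    out[[nm]] <- list(rate = rate,
                      data = data.frame(time = tt, value = v[ok]))
  }
  s <- physio_stream(participant_id, out)
  attr(s, "dropped") <- dropped
  s
}

#' Write a physiological stream to CSV (one file per channel set)
#'
#' Channels are written on their own time base: the union of all channel
#' timestamps forms the `time` column and each channel contributes its value
#' at its own timestamps (other cells empty). A stream written by this
#' function and re-read by [load_physio_csv()] round-trips losslessly.
#'
#' @param stream a [physio_stream()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
save_physio_csv <- function(stream, path) {
  times <- sort(unique(unlist(lapply(stream$channels, function(ch) ch$data$time))))
  df <- data.frame(time = times)
  for (nm in names(stream$channels)) {
    ch <- stream$channels[[nm]]
    v <- rep(NA_real_, length(times))
    v[match(ch$data$time, times)] <- ch$data$value
    df[[nm]] <- v
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Validate a minute-level digital-biomarker table
#'
#' Checks the invariants of the per-minute biomarker records: one record
#' per minute (strictly increasing, 60-second spaced `minute_start`),
#' physiological ranges (pulse 20-250 bpm, respiratory rate 4-60
#' breaths/min, temperature 20-45 C, non-negative counts and steps), and
#' that records flagged as not worn carry no physiology values.
#'
#' @param df data.frame as produced by [generate_physio()] (columns
#'   `minute_start`, `pulse_rate`, `pulse_rate_variability`,
#'   `respiratory_rate`, `activity_counts`, `steps`, `acc_magnitude_sd`,
#'   `activity_class`, `skin_conductance_level`, `wearing`,
#'   `temperature`).
#' @return `df` invisibly; stops with a data error on violation.
#' @export
validate_biomarkers <- function(df) {
  need <- c("minute_start", "pulse_rate", "respiratory_rate",
            "activity_counts", "steps", "activity_class", "wearing",
            "temperature")
  if (!all(need %in% names(df)))
    stop("format error: biomarker table lacks columns ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if (nrow(df) > 1L && any(diff(df$minute_start) != 60))
    stop("data error: biomarker records must be one per minute")
  worn <- df$wearing
  chk <- function(x, lo, hi, what) {
    bad <- worn & !is.na(x) & (x < lo | x > hi)
    if (any(bad)) stop("data error: ", what, " out of range at minute ",
                       df$minute_start[which(bad)[1L]])
  }
  chk(df$pulse_rate, 20, 250, "pulse rate")
  chk(df$respiratory_rate, 4, 60, "respiratory rate")
  chk(df$temperature, 20, 45, "temperature")
  if (any(worn & (df$activity_counts < 0 | df$steps < 0)))
    stop("data error: negative activity counts or steps")
  if (any(!worn & (!is.na(df$pulse_rate) | !is.na(df$temperature))))
    stop("data error: not-worn records must have missing physiology")
  invisible(df)
}

.label_levels <- c("agitation", "preagitation", "normal")
.source_levels <- c("nurse_note", "camera", "manual", "synthetic_truth")

#' Construct an episode label table
#'
#' Labeled intervals `[start, end)` with provenance. Episodes of the same
#' participant and label may not overlap.
#'
#' @param participant_id,start,end,label,source vectors of equal length;
#'   `label` one of `agitation`, `preagitation`, `normal`; `source` one of
#'   `nurse_note`, `camera`, `manual`, `synthetic_truth`.
#' @return data.frame of class `episode_labels`, sorted by `start`.
#' @export
episode_labels <- function(participant_id = character(), start = numeric(),
                           end = numeric(), label = character(),
                           source = character()) {
  df <- data.frame(participant_id = as.character(participant_id),
                   start = as.numeric(start), end = as.numeric(end),
                   label = as.character(label), source = as.character(source),
                   stringsAsFactors = FALSE)
  bad <- setdiff(unique(df$label), .label_levels)
  if (length(bad)) stop("format error: unknown label '", bad[1L], "'")
  bad <- setdiff(unique(df$source), .source_levels)
  if (length(bad)) stop("format error: unknown source '", bad[1L], "'")
  if (any(df$end <= df$start))
    stop("data error: episode end must exceed start (row ",
         which(df$end <= df$start)[1L], ")")
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  # overlap check within participant x label
  if (nrow(df) > 1L) {
    key <- paste(df$participant_id, df$label)
    for (k in unique(key)) {
      sub <- df[key == k, , drop = FALSE]
      if (nrow(sub) > 1L && any(sub$start[-1L] < sub$end[-nrow(sub)]))
        stop("data error: overlapping '", sub$label[1L],
             "' episodes for participant ", sub$participant_id[1L])
    }
  }
  class(df) <- c("episode_labels", "data.frame")
  df
}

#' Load episode labels from a delimited file
#'
#' Accepts CSV with columns `participant_id`, `start`, `end`, `label`,
#' `source` (a `participant` column is accepted as an alias), or JSON-lines
#' with the same keys.
#'
#' @param path file path; JSON-lines detected by `.jsonl`/`.ndjson` suffix.
#' @return an [episode_labels()] table sorted by start.
#' @export
load_labels <- function(path) {
  if (grepl("\\.(jsonl|ndjson)$", path)) {
    rows <- lapply(readLines(path, warn = FALSE), jsonlite::fromJSON)
    df <- do.call(rbind, lapply(rows, as.data.frame))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if ("participant" %in% names(df) && !"participant_id" %in% names(df))
    names(df)[names(df) == "participant"] <- "participant_id"
  need <- c("participant_id", "start", "end", "label", "source")
  if (!all(need %in% names(df)))
    stop("format error: label file must have columns ",
         paste(need, collapse = ", "))
  episode_labels(df$participant_id, df$start, df$end, df$label, df$source)
}

#' Write episode labels as CSV
#' @param labels an [episode_labels()] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_labels <- function(labels, path) {
  utils::write.csv(as.data.frame(labels), path, row.names = FALSE)
  invisible(path)
}

#' Label feature windows from episode intervals
#'
#' A window `[start, end)` is labeled `agitation` when its summed overlap
#' with agitation episodes reaches `overlap_fraction` of the window length;
#' all other windows are `normal`. Pre-agitation intervals are an
#' annotation layer, not a training class: by default windows meeting the
#' overlap rule against pre-agitation episodes are labeled
#' `"preagitation"` so the model layer can hold them out of binary
#' training (labeling them `normal` would poison the negative class, since
#' physiology already sits near agitated levels there). With
#' `preagitation = "merge"` they count as agitation — the early-warning
#' training mode.
#'
#' @param windows data.frame with numeric `window_start`, `window_end`.
#' @param episodes an [episode_labels()] table (may be empty).
#' @param overlap_fraction required overlap fraction in (0, 1]; default 0.5.
#' @param preagitation `"exclude"` (default: own label, held out of binary
#'   training), `"merge"` (counts as agitation) or `"normal"` (folded into
#'   the negative class).
#' @return `windows` with a `label` column
#'   (`"agitation"`/`"preagitation"`/`"normal"`).
#' @export
label_windows <- function(windows, episodes,
                          overlap_fraction = 0.5,
                          preagitation = c("exclude", "merge", "normal")) {
  stopifnot(overlap_fraction > 0, overlap_fraction <= 1)
  preagitation <- match.arg(preagitation)
  overlap_with <- function(labels) {
    ep <- episodes[episodes$label %in% labels, , drop = FALSE]
    vapply(seq_len(nrow(windows)), function(i) {
      ws <- windows$window_start[i]; we <- windows$window_end[i]
      if (!nrow(ep)) return(0)
      sum(pmax(0, pmin(we, ep$end) - pmax(ws, ep$start))) / (we - ws)
    }, 0)
  }
  pos_labels <- if (preagitation == "merge") c("agitation", "preagitation")
                else "agitation"
  lab <- rep("normal", nrow(windows))
  lab[overlap_with(pos_labels) >= overlap_fraction] <- "agitation"
  if (preagitation == "exclude") {
    pre <- overlap_with("preagitation") >= overlap_fraction
    lab[pre & lab != "agitation"] <- "preagitation"
  }
  windows$label <- lab
  windows
}
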