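# Reading and validating the JSON-lines interchange schemas.
#
# One directory per participant with calls.jsonl, screen.jsonl, apps.jsonl,
# wristband.jsonl, phq9.jsonl.  Missing files yield empty streams; malformed
# lines are counted and logged, and only a rejection rate above the
# configured threshold is fatal.  All timestamps are converted to one
# participant-local timezone at load; every clock-time bin downstream is a
# local-clock bin.

STREAM_FILES <- c(call = "calls.jsonl", screen = "screen.jsonl",
                  app = "apps.jsonl", wristband = "wristband.jsonl",
                  phq9 = "phq9.jsonl")

new_event_stream <- function(participant_id, kind, records) {
  structure(list(participant_id = participant_id, kind = kind,
                 records = records),
            class = "event_stream")
}

empty_records <- function(kind) {
  pos <- as.POSIXct(character(), tz = "UTC")
  switch(kind,
    call = data.frame(ts = pos, direction = character(),
                      duration_s = numeric(), peer = character()),
    screen = data.frame(ts = pos, event = character()),
    app = data.frame(ts_start = pos, ts_end = pos, app_id = character(),
                     category = character()),
    wristband = data.frame(ts = pos, type = character(),
                           intensity = numeric(), steps = integer(),
                           heart_rate = numeric()),
    phq9 = data.frame(ts = pos, score = integer()))
}

#' Load and validate one participant's raw streams
#'
#' Reads any subset of the interchange files from `dir`, validates each
#' record against its schema, converts timestamps to `tz`, and returns
#' time-sorted streams.  Records failing validation (bad JSON, missing
#' fields, out-of-range values, heart rate present outside sleep minutes)
#' are rejected and counted; if a file's rejection rate exceeds
#' `reject_threshold` the load aborts naming the file and the first bad
#' line.  Screen events are passed through [clean_screen_events()].
#'
#' @param dir participant directory.
#' @param participant_id id attached to the streams (default: basename).
#' @param tz participant-local timezone for clock-time computations.
#' @param reject_threshold maximum tolerated fraction of malformed lines
#'   per file (default 0.05).
#' @return list with `streams` (named list of `event_stream`s: `call`,
#'   `screen`, `app`, `wristband`), `phq9` (data.frame `ts`, `score`) and
#'   `rejects` (named counts of rejected lines per file).
#' @export
load_participant <- function(dir, participant_id = basename(dir),
                             tz = "UTC", reject_threshold = 0.05) {
  out <- list(); rejects <- c()
  for (kind in names(STREAM_FILES)) {
    path <- file.path(dir, STREAM_FILES[[kind]])
    parsed <- read_jsonl_records(path, kind, tz, reject_threshold)
    rejects[STREAM_FILES[[kind]]] <- parsed$n_reject
    out[[kind]] <- parsed$records
  }
  streams <- lapply(c("call", "screen", "app", "wristband"), function(k)
    new_event_stream(participant_id, k, out[[k]]))
  names(streams) <- c("call", "screen", "app", "wristband")
  streams$screen <- clean_screen_events(streams$screen)
  list(streams = streams, phq9 = out$phq9, rejects = rejects)
}

read_jsonl_records <- function(path, kind, tz, reject_threshold) {
  if (!file.exists(path))
    return(list(records = empty_records(kind), n_reject = 0L))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(list(records = empty_records(kind), n_reject = 0L))
  # fast path: parse the whole file as one JSON array
  df <- tryCatch(
    jsonlite::fromJSON(paste0("[", paste(lines, collapse = ","), "]")),
    error = function(e) NULL)
  bad <- integer(0)
  if (is.null(df)) {                      # per-line fallback
    recs <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      r <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e) NULL)
      if (is.null(r)) bad <- c(bad, i) else recs[[i]] <- r
    }
    ok <- setdiff(seq_along(lines), bad)
    df <- do.call(rbind, lapply(recs[ok],
                                function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  } else {
    ok <- seq_along(lines)
  }
  v <- validate_records(df, kind, tz)
  bad_all <- c(bad, ok[v$bad_rows])
  n_reject <- length(bad_all)
  if (n_reject / length(lines) > reject_threshold)
    stop(sprintf("%s: %d of %d lines rejected (first bad line %d)",
                 path, n_reject, length(lines), min(bad_all)))
  if (n_reject > 0)
    message(sprintf("%s: rejected %d malformed line(s)",
                    basename(path), n_reject))
  rec <- v$records
  tcol <- if (kind == "app") "ts_start" else "ts"
  rec <- rec[order(rec[[tcol]]), , drop = FALSE]  # stable: file order on ties
  rownames(rec) <- NULL
  list(records = rec, n_reject = n_reject)
}

# schema validation; returns cleaned records and indices of bad rows
validate_records <- function(df, kind, tz) {
  tmpl <- empty_records(kind)
  if (is.null(df) || nrow(df) == 0)
    return(list(records = tmpl, bad_rows = integer(0)))
  need <- names(tmpl)
  for (m in setdiff(need, names(df))) df[[m]] <- NA
  bad <- rep(FALSE, nrow(df))
  tcols <- intersect(c("ts", "ts_start", "ts_end"), need)
  for (tc in tcols) {
    df[[tc]] <- parse_ts(as.character(df[[tc]]), tz)
    bad <- bad | is.na(df[[tc]])
  }
  for (nc in intersect(c("duration_s", "intensity", "heart_rate", "score",
                         "steps"), need))
    df[[nc]] <- suppressWarnings(as.numeric(df[[nc]]))
  bad <- bad | switch(kind,
    call = !(df$direction %in% c("incoming", "outgoing", "rejected")) |
      is.na(df$duration_s) | df$duration_s < 0,
    screen = !(df$event %in% c("on", "off")),
    app = is.na(df$app_id),
    wristband = !(df$type %in% c("activity", "light_sleep", "deep_sleep",
                                 "not_worn")) |
      is.na(df$steps) | df$steps < 0 |
      (!is.na(df$heart_rate) &
         !(df$type %in% c("light_sleep", "deep_sleep"))),
    phq9 = is.na(df$score) |
      df$score < 0 | df$score > 27 | df$score != round(df$score))
  bad[is.na(bad)] <- TRUE
  if (kind == "app") {
    unknown <- !(df$category %in% APP_CATEGORIES) & !bad
    if (any(unknown)) {
      warning(sprintf("%d app record(s) with unknown category assigned to 'others'",
                      sum(unknown)))
      df$category[unknown] <- "others"
    }
  }
  if (kind == "phq9") df$score <- as.integer(df$score)
  if (kind == "wristband") {
    df$steps <- as.integer(df$steps)
    df$heart_rate <- as.numeric(df$heart_rate)
    if (!"intensity" %in% names(df) || all(is.na(df$intensity)))
      df$intensity <- 0
  }
  list(records = df[!bad, need, drop = FALSE], bad_rows = which(bad))
}

#' Repair a screen event stream to strict on/off alternation
#'
#' Screen sessions are defined by alternating activation ("on") and lock
#' ("off") events.  Raw logs can carry duplicates (reboots, logging races):
#' consecutive duplicate events are collapsed keeping the first, a leading
#' unmatched "off" is dropped, and a trailing unmatched "on" is dropped so
#' the result is a sequence of complete on/off pairs.  Idempotent.
#'
#' @param stream an `event_stream` of kind `screen`.
#' @return the repaired stream.
#' @export
clean_screen_events <- function(stream) {
  stopifnot(stream$kind == "screen")
  rec <- stream$records
  if (is.null(rec) || nrow(rec) == 0) return(stream)
  keep <- c(TRUE, rec$event[-1] != rec$event[-nrow(rec)])
  rec <- rec[keep, , drop = FALSE]
  if (nrow(rec) > 0 && rec$event[1] == "off")
    rec <- rec[-1, , drop = FALSE]
  if (nrow(rec) %% 2 == 1)                   # trailing unmatched "on"
    rec <- rec[-nrow(rec), , drop = FALSE]
  rownames(rec) <- NULL
  stream$records <- rec
  stream
}
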