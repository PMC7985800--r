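# Sample formation and mood-stability labeling.
#
# Every run of three consecutive PHQ-9 submissions defines one candidate data
# sample: period 1 spans [t1, t2), period 2 spans [t2, t3).  A candidate is
# discarded if either period is shorter than 7 days (the PHQ-9 reflects
# roughly the past week) or if a required stream has fewer than 3 effective
# days in either period.

MOODSTAB_LABELS <- c("swing_drastic", "swing_moderate",
                     "steady_remission", "steady_depressed", "unlabeled")

#' Assign a mood-stability label to a PHQ-9 triple
#'
#' Labels three consecutive PHQ-9 total scores using the study criteria:
#' Swing-drastic (range \eqn{\ge} 10), Swing-moderate (range \eqn{\ge} 5),
#' Steady-remission (all three \eqn{\le} 5), Steady-depressed (all three
#' \eqn{\ge} 11 and range < 5).  The criteria overlap, so rules are applied
#' in the fixed precedence Drastic, Moderate, Remission, Depressed; a triple
#' matching no rule is `"unlabeled"`.  Under this precedence Moderate
#' effectively means 5 \eqn{\le} range < 10 and the four labeled classes are
#' disjoint.
#'
#' @param s1,s2,s3 integer PHQ-9 total scores in `[0, 27]` (vectorized).
#' @return character vector of labels, one of
#'   `"swing_drastic"`, `"swing_moderate"`, `"steady_remission"`,
#'   `"steady_depressed"`, `"unlabeled"`.
#' @examples
#' assign_label(5, 15, 8)    # swing_drastic
#' assign_label(12, 14, 13)  # steady_depressed
#' @export
assign_label <- function(s1, s2, s3) {
  s <- cbind(s1, s2, s3)
  if (any(!is.finite(s)) || any(s < 0 | s > 27) || any(s != round(s)))
    stop("PHQ-9 scores must be integers in [0, 27]")
  hi <- pmax(s1, s2, s3)
  lo <- pmin(s1, s2, s3)
  rng <- hi - lo
  out <- rep("unlabeled", length(rng))
  out[hi >= 11 & lo >= 11 & rng < 5] <- "steady_depressed"
  out[hi <= 5] <- "steady_remission"
  out[rng >= 5] <- "swing_moderate"
  out[rng >= 10] <- "swing_drastic"
  out
}

#' Build candidate two-period samples from a PHQ-9 series
#'
#' Slides a window of three consecutive submissions (stride 1) over the
#' time-sorted series; each window yields one candidate sample with
#' period 1 = `[t1, t2)` and period 2 = `[t2, t3)`.  Candidates with either
#' period shorter than `min_period_days` are discarded.  Overlapping samples
#' are allowed: one submission can appear in up to three windows.
#'
#' @param phq9 data.frame with columns `ts` (POSIXct) and `score`.
#' @param min_period_days minimum period length in days (default 7;
#'   measured as 7 x 24 h between submission timestamps).
#' @return data.frame with one row per retained candidate: `t1 t2 t3 s1 s2 s3
#'   label period1_days period2_days`.  Zero rows if fewer than 3 records.
#' @export
make_samples <- function(phq9, min_period_days = 7) {
  n <- nrow(phq9)
  empty <- data.frame(t1 = as.POSIXct(character()), t2 = as.POSIXct(character()),
                      t3 = as.POSIXct(character()),
                      s1 = integer(), s2 = integer(), s3 = integer(),
                      label = character(),
                      period1_days = numeric(), period2_days = numeric())
  if (is.null(n) || n < 3) return(empty)
  if (is.unsorted(phq9$ts)) stop("phq9 records must be time-sorted")
  i <- seq_len(n - 2)
  d1 <- as.numeric(difftime(phq9$ts[i + 1], phq9$ts[i], units = "days"))
  d2 <- as.numeric(difftime(phq9$ts[i + 2], phq9$ts[i + 1], units = "days"))
  keep <- d1 >= min_period_days & d2 >= min_period_days
  i <- i[keep]
  if (length(i) == 0) return(empty)
  data.frame(
    t1 = phq9$ts[i], t2 = phq9$ts[i + 1], t3 = phq9$ts[i + 2],
    s1 = phq9$score[i], s2 = phq9$score[i + 1], s3 = phq9$score[i + 2],
    label = assign_label(phq9$score[i], phq9$score[i + 1], phq9$score[i + 2]),
    period1_days = d1[keep], period2_days = d2[keep],
    stringsAsFactors = FALSE)
}

#' Count effective days of a stream within a period
#'
#' An effective day is a local calendar day carrying enough data of the
#' stream's kind: for phone streams (call, screen, app) at least
#' `min_events` records; for the wristband at least `min_worn_minutes`
#' worn minute-packets (any type except `"not_worn"`).
#'
#' @param stream an `event_stream` (see [load_participant()]).
#' @param period POSIXct length-2 vector `[start, end)`.
#' @param min_events phone-stream threshold (default 1 record).
#' @param min_worn_minutes wristband threshold (default 240 packets).
#' @return integer count of effective days.
#' @export
effective_days <- function(stream, period, min_events = 1,
                           min_worn_minutes = 240) {
  rec <- stream$records
  if (is.null(rec) || nrow(rec) == 0) return(0L)
  ts <- if (stream$kind == "app") rec$ts_start else rec$ts
  in_p <- ts >= period[1] & ts < period[2]
  rec <- rec[in_p, , drop = FALSE]
  if (nrow(rec) == 0) return(0L)
  if (stream$kind == "wristband") {
    worn <- rec$type != "not_worn"
    days <- table(local_date(rec$ts[worn]))
    sum(days >= min_worn_minutes)
  } else {
    ts <- if (stream$kind == "app") rec$ts_start else rec$ts
    days <- table(local_date(ts))
    sum(days >= min_events)
  }
}

#' Build labeled, quality-filtered samples for one participant
#'
#' Combines [make_samples()] with per-stream effective-day counting.  The
#' effective-day discard (at least `min_effective_days` per period) is
#' evaluated later, per data-type combination, because a sample can be usable
#' for a wristband-only analysis but not a call-log analysis; this function
#' records the counts.
#'
#' @param streams named list of `event_stream`s (`call`, `screen`, `app`,
#'   `wristband`) as returned by [load_participant()].
#' @param phq9 PHQ-9 data.frame (`ts`, `score`).
#' @param participant_id id copied onto each row.
#' @param min_period_days,min_events,min_worn_minutes see [make_samples()]
#'   and [effective_days()].
#' @return data.frame of candidate samples with effective-day columns
#'   `eff_<stream>_p1`, `eff_<stream>_p2`.
#' @export
build_samples <- function(streams, phq9, participant_id = "unknown",
                          min_period_days = 7, min_events = 1,
                          min_worn_minutes = 240) {
  smp <- make_samples(phq9, min_period_days)
  kinds <- c("call", "screen", "app", "wristband")
  for (k in kinds) {
    smp[[paste0("eff_", k, "_p1")]] <- integer(nrow(smp))
    smp[[paste0("eff_", k, "_p2")]] <- integer(nrow(smp))
  }
  if (nrow(smp) == 0) {
    smp$participant_id <- character(0)
    return(smp[c("participant_id", setdiff(names(smp), "participant_id"))])
  }
  for (i in seq_len(nrow(smp))) {
    for (k in kinds) {
      st <- streams[[k]]
      if (is.null(st)) st <- list(kind = k, records = NULL)
      smp[[paste0("eff_", k, "_p1")]][i] <-
        effective_days(st, c(smp$t1[i], smp$t2[i]), min_events, min_worn_minutes)
      smp[[paste0("eff_", k, "_p2")]][i] <-
        effective_days(st, c(smp$t2[i], smp$t3[i]), min_events, min_worn_minutes)
    }
  }
  smp$participant_id <- participant_id
  smp[c("participant_id", setdiff(names(smp), "participant_id"))]
}
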