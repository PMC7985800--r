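# Phone-derived period features: call logs, screen sessions, app usage.
#
# Naming grammar: <stream>.<base>[.<subgroup>], e.g. call.incoming.count,
# app.instant_messaging.duration_00_03.  Features without a basis (entropy
# of zero calls, mean duration of zero sessions) are NaN, never fabricated
# zeros; imputation is the bench module's job.

CALL_TYPES <- c("incoming", "outgoing", "rejected", "all")
BIN_EDGES <- seq(0, 24, by = 3)
BIN_NAMES <- sprintf("%02d_%02d", BIN_EDGES[-9], BIN_EDGES[-1])

nan_unless <- function(cond, value) if (cond) value else NaN

#' Call-log features for one period
#'
#' For each call type (incoming, outgoing, rejected, and all calls):
#' count, total and mean duration (duration features for rejected calls are
#' NaN — a rejected call has no duration), number of distinct peers,
#' Shannon entropy of callers (each peer an event, weighted by number of
#' calls), and circular mean/SD of the clock hour of calls.
#'
#' @param calls call records data.frame (`ts`, `direction`, `duration_s`,
#'   `peer`).
#' @param period POSIXct length-2 `[start, end)`.
#' @return named numeric vector of period features.
#' @export
call_features <- function(calls, period) {
  out <- c()
  if (is.null(calls)) calls <- empty_records("call")
  calls <- calls[calls$ts >= period[1] & calls$ts < period[2], , drop = FALSE]
  for (type in CALL_TYPES) {
    sub <- if (type == "all") calls else
      calls[calls$direction == type, , drop = FALSE]
    n <- nrow(sub)
    pre <- paste0("call.", type, ".")
    out[paste0(pre, "count")] <- n
    has_dur <- n > 0 && type != "rejected"
    out[paste0(pre, "total_duration")] <-
      nan_unless(has_dur, sum(sub$duration_s[sub$direction != "rejected"]))
    out[paste0(pre, "mean_duration")] <-
      nan_unless(has_dur && any(sub$direction != "rejected"),
                 mean(sub$duration_s[sub$direction != "rejected"]))
    out[paste0(pre, "distinct_peers")] <-
      nan_unless(n > 0, length(unique(sub$peer)))
    out[paste0(pre, "peer_entropy")] <-
      if (n > 0) shannon_entropy(table(sub$peer)) else NaN
    cs <- circular_stats(clock_hour(sub$ts))
    out[paste0(pre, "hour_mean")] <- cs$mean
    out[paste0(pre, "hour_sd")] <- cs$sd
  }
  out
}

# on/off pairs -> session intervals clipped to the period
screen_sessions <- function(screen, period) {
  if (is.null(screen) || nrow(screen) < 2)
    return(data.frame(start = as.POSIXct(character(), tz = "UTC"),
                      end = as.POSIXct(character(), tz = "UTC")))
  on <- screen$ts[screen$event == "on"]
  off <- screen$ts[screen$event == "off"]
  n <- min(length(on), length(off))
  s <- data.frame(start = on[seq_len(n)], end = off[seq_len(n)])
  s <- s[s$end > period[1] & s$start < period[2], , drop = FALSE]
  s$start <- pmax(s$start, period[1])
  s$end <- pmin(s$end, period[2])
  s
}

#' Screen-usage features for one period
#'
#' Sessions are the spans between an "on" and the next "off" event.
#' Reports the mean and median over days of the daily session count and
#' daily total usage duration, the mean session duration, and the share of
#' total usage falling in the morning (06-12), afternoon (12-18) and night
#' (18-24) clock windows.  Days with no screen data are excluded from the
#' per-day averages (non-compliance is not inactivity).  Sessions crossing
#' a window boundary are split proportionally.
#'
#' @param screen cleaned screen records (`ts`, `event`, alternating).
#' @param period POSIXct length-2 `[start, end)`.
#' @return named numeric vector.
#' @export
screen_features <- function(screen, period) {
  s <- screen_sessions(screen, period)
  out <- c()
  n <- nrow(s)
  out["screen.session_count"] <- n
  if (n == 0) {
    nmn <- c("daily_count_mean", "daily_count_median", "daily_duration_mean",
             "daily_duration_median", "session_duration_mean",
             "morning_ratio", "afternoon_ratio", "night_ratio")
    out[paste0("screen.", nmn)] <- NaN
    return(out)
  }
  dur <- as.numeric(s$end) - as.numeric(s$start)
  day <- local_date(s$start)
  daily_n <- tapply(dur, day, length)
  daily_d <- tapply(dur, day, sum)
  out["screen.daily_count_mean"] <- mean(daily_n)
  out["screen.daily_count_median"] <- stats::median(daily_n)
  out["screen.daily_duration_mean"] <- mean(daily_d)
  out["screen.daily_duration_median"] <- stats::median(daily_d)
  out["screen.session_duration_mean"] <- mean(dur)
  total <- sum(dur)
  out["screen.morning_ratio"] <- intervals_bin_overlap(s$start, s$end, 6, 12) / total
  out["screen.afternoon_ratio"] <- intervals_bin_overlap(s$start, s$end, 12, 18) / total
  out["screen.night_ratio"] <- intervals_bin_overlap(s$start, s$end, 18, 24) / total
  out
}

#' App-usage features for one period
#'
#' For each of the eight app groups (seven assignable categories plus
#' "all"): mean and SD of session durations, and the usage duration and
#' session count in each of the eight 3-hour clock bins (sessions spanning
#' a bin boundary contribute duration proportionally; a session is counted
#' in the bin of its start).  Additionally the cross-category Shannon
#' entropy is computed twice — once with session counts and once with
#' durations as event weights — plus the instant-messaging share of total
#' app duration.
#'
#' @param apps app session records (`ts_start`, `ts_end`, `app_id`,
#'   `category`).
#' @param period POSIXct length-2 `[start, end)`.
#' @return named numeric vector.
#' @export
app_features <- function(apps, period) {
  if (is.null(apps)) apps <- empty_records("app")
  a <- apps[apps$ts_end > period[1] & apps$ts_start < period[2], , drop = FALSE]
  if (nrow(a) > 0) {
    a$ts_start <- pmax(a$ts_start, period[1])
    a$ts_end <- pmin(a$ts_end, period[2])
  }
  out <- c()
  cat_dur <- numeric(length(APP_CATEGORIES)); names(cat_dur) <- APP_CATEGORIES
  cat_n <- cat_dur
  for (g in APP_GROUPS) {
    sub <- if (g == "all") a else a[a$category == g, , drop = FALSE]
    n <- nrow(sub)
    pre <- paste0("app.", g, ".")
    dur <- as.numeric(sub$ts_end) - as.numeric(sub$ts_start)
    if (g != "all") { cat_dur[g] <- sum(dur); cat_n[g] <- n }
    out[paste0(pre, "count")] <- n
    out[paste0(pre, "duration_mean")] <- nan_unless(n > 0, mean(dur))
    out[paste0(pre, "duration_sd")] <-
      if (n > 1) stats::sd(dur) else NaN
    start_h <- clock_hour(sub$ts_start)
    for (b in seq_along(BIN_NAMES)) {
      h0 <- BIN_EDGES[b]; h1 <- BIN_EDGES[b + 1]
      d <- if (n == 0) 0 else
        intervals_bin_overlap(sub$ts_start, sub$ts_end, h0, h1)
      cnt <- if (n == 0) 0 else sum(start_h >= h0 & start_h < h1)
      out[paste0(pre, "duration_", BIN_NAMES[b])] <- d
      out[paste0(pre, "count_", BIN_NAMES[b])] <- cnt
    }
  }
  out["app.category_entropy_count"] <-
    if (sum(cat_n) > 0) shannon_entropy(cat_n) else NaN
  out["app.category_entropy_duration"] <-
    if (sum(cat_dur) > 0) shannon_entropy(cat_dur) else NaN
  out["app.im_ratio"] <- if (sum(cat_dur) > 0)
    cat_dur[["instant_messaging"]] / sum(cat_dur) else NaN
  out
}

#' Aggregate two periods of features into sample features
#'
#' For every base feature with values \eqn{a} (period 1) and \eqn{b}
#' (period 2) emits `<name>.diff` \eqn{= b - a}, `<name>.mean`
#' \eqn{= (a+b)/2} and `<name>.sd` \eqn{= |b-a|/\sqrt{2}} (two-point sample
#' SD, n-1 convention).  A NaN in either period propagates to all three.
#'
#' @param pf1,pf2 named numeric vectors with identical name sets.
#' @return named numeric vector of length `3 * length(pf1)`.
#' @export
aggregate_periods <- function(pf1, pf2) {
  if (!identical(sort(names(pf1)), sort(names(pf2))))
    stop("period feature name sets differ")
  pf2 <- pf2[names(pf1)]
  fin <- is.finite(pf1) & is.finite(pf2)
  d <- m <- s <- rep(NaN, length(pf1))
  d[fin] <- pf2[fin] - pf1[fin]
  m[fin] <- (pf1[fin] + pf2[fin]) / 2
  s[fin] <- abs(d[fin]) / sqrt(2)
  out <- c(rbind(d, m, s))
  names(out) <- c(rbind(paste0(names(pf1), ".diff"),
                        paste0(names(pf1), ".mean"),
                        paste0(names(pf1), ".sd")))
  out
}
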