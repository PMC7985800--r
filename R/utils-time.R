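# Canonical time handling.  All timestamps are POSIXct in a single
# participant-local timezone (default UTC); clock-time bins (the eight 3-hour
# bins, morning/afternoon/night) are computed on the local clock.

TS_FORMAT <- "%Y-%m-%dT%H:%M:%S%z"

#' Format timestamps as ISO-8601 with timezone offset
#'
#' @param ts POSIXct vector.
#' @return character vector like `"2024-01-01T08:30:00+0000"`.
#' @keywords internal
format_ts <- function(ts) {
  format(ts, format = "%Y-%m-%dT%H:%M:%S%z")
}

#' Parse ISO-8601 timestamps
#'
#' @param x character vector with timezone offsets (`+0000` or `+00:00`).
#' @param tz local timezone used for clock-time computations.
#' @return POSIXct vector in `tz`.
#' @keywords internal
parse_ts <- function(x, tz = "UTC") {
  x <- sub("([+-][0-9]{2}):([0-9]{2})$", "\\1\\2", x)
  out <- as.POSIXct(x, format = TS_FORMAT, tz = tz)
  if (anyNA(out) && !anyNA(x)) {
    # tolerate timestamps without an offset: read as local time
    miss <- is.na(out)
    out[miss] <- as.POSIXct(x[miss], format = "%Y-%m-%dT%H:%M:%S", tz = tz)
  }
  out
}

#' Clock hour of a timestamp
#'
#' Fractional hour in [0, 24) on the local clock.
#' @keywords internal
clock_hour <- function(ts) {
  lt <- as.POSIXlt(ts)
  lt$hour + lt$min / 60 + lt$sec / 3600
}

#' Local calendar date of a timestamp
#' @keywords internal
local_date <- function(ts) {
  as.Date(format(ts, "%Y-%m-%d"))
}

#' Seconds of overlap between an interval and a clock-hour bin, per day
#'
#' Splits the span `[start, end)` over local calendar days and accumulates the
#' overlap with the daily clock window `[h0, h1)` (hours).  Sessions crossing
#' a bin boundary are split proportionally so total duration is conserved.
#'
#' @param start,end POSIXct scalars, `start <= end`.
#' @param h0,h1 clock hours, `0 <= h0 < h1 <= 24`.
#' @return seconds of overlap (numeric scalar).
#' @keywords internal
interval_bin_overlap <- function(start, end, h0, h1) {
  if (end <= start) return(0)
  total <- 0
  d <- trunc(start, units = "days")
  while (d < end) {
    w0 <- d + h0 * 3600
    w1 <- d + h1 * 3600
    lo <- max(as.numeric(start), as.numeric(w0))
    hi <- min(as.numeric(end), as.numeric(w1))
    if (hi > lo) total <- total + (hi - lo)
    d <- d + 86400
  }
  total
}

#' Total overlap of many intervals with a daily clock window
#'
#' Vectorized form of [interval_bin_overlap()]: sums, over all intervals,
#' the seconds falling inside the local clock window `[h0, h1)` of any day.
#'
#' @param start,end POSIXct vectors of equal length.
#' @param h0,h1 clock hours.
#' @return total seconds (numeric scalar).
#' @keywords internal
intervals_bin_overlap <- function(start, end, h0, h1) {
  if (length(start) == 0) return(0)
  s <- as.numeric(start); e <- as.numeric(end)
  d0 <- as.numeric(start) - (clock_hour(start) * 3600)  # local midnight
  total <- 0
  off <- 0
  while (any(e > d0 + off)) {
    w0 <- d0 + off + h0 * 3600
    w1 <- d0 + off + h1 * 3600
    total <- total + sum(pmax(0, pmin(e, w1) - pmax(s, w0)))
    off <- off + 86400
  }
  total
}

#' Circular mean and SD of clock values
#'
#' Hours (or other periodic values) are mapped to angles on a circle of the
#' given period; the mean direction is mapped back to `[0, period)` and the
#' circular SD is `sqrt(-2 log R)` scaled to the period's units.
#'
#' @param hours numeric vector.
#' @param period circle period in the same units (24 for clock hours).
#' @return list with `mean` and `sd`; both `NaN` on empty input, `sd` is 0
#'   for a single value.
#' @keywords internal
circular_stats <- function(hours, period = 24) {
  hours <- hours[is.finite(hours)]
  n <- length(hours)
  if (n == 0) return(list(mean = NaN, sd = NaN))
  theta <- 2 * pi * hours / period
  s <- mean(sin(theta)); c <- mean(cos(theta))
  m <- atan2(s, c) %% (2 * pi)
  if (2 * pi - m < 1e-9) m <- 0  # snap the wrap so 24 - eps reports as 0
  r <- sqrt(s^2 + c^2)
  sd <- if (r >= 1 - 1e-12) 0 else sqrt(-2 * log(r)) * period / (2 * pi)
  list(mean = m * period / (2 * pi), sd = sd)
}
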