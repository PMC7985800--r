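# Wearable period features: sleep architecture, step counts, and nightly
# heart-rate cosinor rhythms from minute-packets.

#' Segment wristband minute-packets into sleep nights
#'
#' A night is a maximal run of sleep-typed minutes (light or deep); runs
#' separated by a gap of at most `bridge_min` minutes (brief awakenings,
#' bathroom trips) are merged.  Runs with fewer than `min_night_min` sleep
#' minutes (naps) are flagged invalid and excluded from summaries.  A night
#' belongs to the local calendar date of its onset.
#'
#' @param wristband minute-packet records (`ts`, `type`, ...).
#' @param period POSIXct length-2 `[start, end)`.
#' @param bridge_min gap-merging threshold in minutes (default 60).
#' @param min_night_min minimum sleep minutes for a valid night (default 180).
#' @return data.frame with one row per run: `date onset wake light_min
#'   deep_min total_min valid`.
#' @export
segment_nights <- function(wristband, period, bridge_min = 60,
                           min_night_min = 180) {
  empty <- data.frame(date = as.Date(character()),
                      onset = as.POSIXct(character(), tz = "UTC"),
                      wake = as.POSIXct(character(), tz = "UTC"),
                      light_min = integer(), deep_min = integer(),
                      total_min = integer(), valid = logical())
  if (is.null(wristband) || nrow(wristband) == 0) return(empty)
  w <- wristband[wristband$ts >= period[1] & wristband$ts < period[2] &
                   wristband$type %in% c("light_sleep", "deep_sleep"), ,
                 drop = FALSE]
  if (nrow(w) == 0) return(empty)
  gap <- c(Inf, diff(as.numeric(w$ts)))
  run <- cumsum(gap > bridge_min * 60)
  nights <- lapply(split(seq_len(nrow(w)), run), function(i) {
    sub <- w[i, , drop = FALSE]
    light <- sum(sub$type == "light_sleep")
    deep <- sum(sub$type == "deep_sleep")
    data.frame(date = local_date(sub$ts[1]), onset = sub$ts[1],
               wake = sub$ts[nrow(sub)] + 60,
               light_min = light, deep_min = deep,
               total_min = light + deep,
               valid = (light + deep) >= min_night_min)
  })
  out <- do.call(rbind, nights)
  rownames(out) <- NULL
  out
}

#' Sleep features for one period
#'
#' Over valid nights: mean/median/SD of light, deep and total sleep
#' minutes; mean light/total and deep/total ratios (sleep-quality proxies);
#' and circular means of the sleep-onset and wake clock times.  SD over a
#' single night is NaN (n-1 convention).  Zero valid nights yields all NaN.
#'
#' @param nights output of [segment_nights()].
#' @param period unused (signature symmetry); kept for the manifest.
#' @return named numeric vector.
#' @export
sleep_features <- function(nights, period = NULL) {
  v <- nights[nights$valid, , drop = FALSE]
  out <- c()
  out["sleep.n_nights"] <- nrow(v)
  amds <- function(x) c(mean = mean(x), median = stats::median(x),
                        sd = if (length(x) > 1) stats::sd(x) else NaN)
  for (comp in c("light", "deep", "total")) {
    x <- if (nrow(v) > 0) v[[paste0(comp, "_min")]] else numeric(0)
    st <- if (length(x) > 0) amds(x) else c(mean = NaN, median = NaN, sd = NaN)
    out[paste0("sleep.", comp, "_", names(st))] <- st
  }
  if (nrow(v) > 0) {
    out["sleep.light_ratio"] <- mean(v$light_min / v$total_min)
    out["sleep.deep_ratio"] <- mean(v$deep_min / v$total_min)
    out["sleep.onset_hour"] <- circular_stats(clock_hour(v$onset))$mean
    out["sleep.wake_hour"] <- circular_stats(clock_hour(v$wake))$mean
  } else {
    out[c("sleep.light_ratio", "sleep.deep_ratio",
          "sleep.onset_hour", "sleep.wake_hour")] <- NaN
  }
  out
}

#' Step-count features for one period
#'
#' The period's total step count; mean/median/SD of daily totals; and
#' mean/median/SD of the daily totals within each of the eight 3-hour
#' clock bins.  Days with no worn packets are excluded from daily
#' statistics.  An empty period yields total 0 and NaN statistics.
#'
#' @param wristband minute-packet records.
#' @param period POSIXct length-2 `[start, end)`.
#' @return named numeric vector.
#' @export
step_features <- function(wristband, period) {
  out <- c()
  if (is.null(wristband)) wristband <- empty_records("wristband")
  w <- wristband[wristband$ts >= period[1] & wristband$ts < period[2] &
                   wristband$type != "not_worn", , drop = FALSE]
  out["step.total"] <- if (nrow(w) > 0) sum(w$steps) else 0
  amds <- function(x) c(mean = mean(x), median = stats::median(x),
                        sd = if (length(x) > 1) stats::sd(x) else NaN)
  if (nrow(w) == 0) {
    out[paste0("step.daily_", c("mean", "median", "sd"))] <- NaN
    for (b in BIN_NAMES)
      out[paste0("step.", b, "_", c("mean", "median", "sd"))] <- NaN
    return(out)
  }
  day <- local_date(w$ts)
  daily <- tapply(w$steps, day, sum)
  st <- amds(as.numeric(daily))
  out[paste0("step.daily_", names(st))] <- st
  hb <- findInterval(clock_hour(w$ts), BIN_EDGES, rightmost.closed = TRUE)
  for (b in seq_along(BIN_NAMES)) {
    sel <- hb == b
    # per-day totals within the bin; a day with worn data but no packets in
    # this bin contributes a genuine zero
    x <- tapply(ifelse(sel, w$steps, 0L), day, sum)
    st <- amds(as.numeric(x))
    out[paste0("step.", BIN_NAMES[b], "_", names(st))] <- st
  }
  out
}

#' Fit a 24-hour cosinor to one night's heart rate
#'
#' Least-squares fit of \eqn{y(t) = M + A\cos(2\pi (t - \phi)/P)} via the
#' linearization \eqn{y = M + \beta_1\cos(\omega t) + \beta_2\sin(\omega t)}
#' with \eqn{t} the local clock hour; \eqn{A = \sqrt{\beta_1^2+\beta_2^2}},
#' \eqn{\phi = (P/2\pi)\,\mathrm{atan2}(\beta_2, \beta_1) \bmod P}, and
#' \eqn{r^2 = 1 - SSE/SST}.  Fitting a 24-h cosine to a sub-24-h window is
#' ill-conditioned by construction; `n_points` and `r2` are retained so
#' selection can discount poor fits.
#'
#' @param ts POSIXct timestamps of sleeping heart-rate minutes.
#' @param hr heart-rate values (bpm).
#' @param period_h cosine period in hours (default 24).
#' @param min_points minimum observations (default 10); fewer returns NULL.
#' @return object of class `cosinor_fit` (`mesor`, `amplitude`,
#'   `acrophase`, `r2`, `n_points`) or NULL.
#' @export
fit_cosinor <- function(ts, hr, period_h = 24, min_points = 10) {
  keep <- is.finite(hr)
  ts <- ts[keep]; hr <- hr[keep]
  n <- length(hr)
  if (n < min_points) return(NULL)
  # unwrapped hours since local midnight of the first observation so the
  # regressor is continuous across midnight
  t0 <- as.POSIXct(trunc(ts[1], "days"))
  th <- as.numeric(difftime(ts, t0, units = "hours"))
  if (stats::var(hr) == 0) {
    fit <- list(mesor = hr[1], amplitude = 0, acrophase = 0, r2 = 0,
                n_points = n)
    class(fit) <- "cosinor_fit"
    return(fit)
  }
  om <- 2 * pi / period_h
  X <- cbind(1, cos(om * th), sin(om * th))
  beta <- stats::lm.fit(X, hr)$coefficients
  pred <- X %*% beta
  sse <- sum((hr - pred)^2)
  sst <- sum((hr - mean(hr))^2)
  amp <- sqrt(beta[2]^2 + beta[3]^2)
  phi <- (atan2(beta[3], beta[2]) * period_h / (2 * pi)) %% period_h
  fit <- list(mesor = unname(beta[1]), amplitude = unname(amp),
              acrophase = unname(phi), r2 = max(0, min(1, 1 - sse / sst)),
              n_points = n)
  class(fit) <- "cosinor_fit"
  fit
}

#' Nightly heart-rate cosinor features for one period
#'
#' Fits one cosinor per valid night (heart rate exists only during sleep
#' minutes) and summarizes mesor, amplitude, acrophase and \eqn{r^2} across
#' nights with mean/median/SD.  Acrophase, a clock time, is averaged
#' circularly; its median and SD are computed on values unwrapped around
#' the circular mean.  SD over one night is NaN.
#'
#' @param wristband minute-packet records.
#' @param period POSIXct length-2 `[start, end)`.
#' @param nights optional precomputed [segment_nights()] output.
#' @param ... passed to [segment_nights()] / [fit_cosinor()].
#' @return named numeric vector.
#' @export
heart_rate_features <- function(wristband, period, nights = NULL, ...) {
  if (is.null(nights)) nights <- segment_nights(wristband, period)
  fits <- cosinor_by_night(wristband, nights, ...)
  out <- c()
  out["hr.n_fits"] <- length(fits)
  get <- function(f) vapply(fits, function(x) x[[f]], 0)
  amds <- function(x) c(mean = mean(x), median = stats::median(x),
                        sd = if (length(x) > 1) stats::sd(x) else NaN)
  for (p in c("mesor", "amplitude", "r2")) {
    st <- if (length(fits) > 0) amds(get(p)) else
      c(mean = NaN, median = NaN, sd = NaN)
    out[paste0("hr.", p, "_", names(st))] <- st
  }
  if (length(fits) > 0) {
    phi <- get("acrophase")
    cm <- circular_stats(phi)$mean
    un <- ((phi - cm + 12) %% 24) - 12  # unwrap around circular mean
    out["hr.acrophase_mean"] <- cm
    out["hr.acrophase_median"] <- (cm + stats::median(un)) %% 24
    out["hr.acrophase_sd"] <- if (length(phi) > 1) stats::sd(un) else NaN
  } else {
    out[paste0("hr.acrophase_", c("mean", "median", "sd"))] <- NaN
  }
  out
}

cosinor_by_night <- function(wristband, nights, ...) {
  v <- nights[nights$valid, , drop = FALSE]
  fits <- list()
  for (i in seq_len(nrow(v))) {
    sel <- wristband$ts >= v$onset[i] & wristband$ts < v$wake[i] &
      wristband$type %in% c("light_sleep", "deep_sleep")
    f <- fit_cosinor(wristband$ts[sel], wristband$heart_rate[sel], ...)
    if (!is.null(f)) fits[[length(fits) + 1]] <- f
  }
  fits
}
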