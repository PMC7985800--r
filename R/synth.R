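# Synthetic cohort generator.
#
# Emulates the raw streams of a passive-sensing depression study: call logs,
# screen on/off events, categorized app-usage sessions, wristband
# minute-packets (activity / light sleep / deep sleep / not worn, heart rate
# present only during sleep minutes), and irregular biweekly-ish PHQ-9
# submissions.  A latent scenario shifts behavioral regimes at the middle
# PHQ-9 time for Swing participants so the downstream two-period difference
# statistics carry signal.

APP_CATEGORIES <- c("instant_messaging", "social_networking", "shopping",
                    "entertainment", "music", "food_delivery", "others")
APP_GROUPS <- c(APP_CATEGORIES, "all")

SCENARIOS <- c("steady_remission", "steady_depressed",
               "swing_drastic", "swing_moderate", "null_effect")

# clock-hour intensity profiles (relative weights per hour 0..23)
.hour_profile <- list(
  call   = c(.05, .02, .02, .02, .02, .05, .2, .5, 1, 1.2, 1.2, 1.2,
             1, 1, 1, 1, 1.2, 1.3, 1.5, 1.5, 1.2, .8, .4, .1),
  screen = c(.2, .1, .05, .05, .05, .1, .4, 1, 1.2, 1.2, 1.2, 1.3,
             1.3, 1.1, 1, 1, 1.1, 1.2, 1.5, 1.8, 1.8, 1.5, 1, .5),
  steps  = c(.02, .01, .01, .01, .01, .05, .3, 1.2, 1.5, 1, .8, 1.2,
             1.3, .8, .7, .7, .8, 1.4, 1.5, 1, .7, .5, .2, .05)
)

#' Construct a synthetic participant profile
#'
#' Baseline behavioral rates for one simulated participant.  Defaults
#' describe a moderately active adult: a handful of calls per day, roughly
#' 40 screen unlocks, app use dominated by instant messaging, ~6000 daily
#' steps, sleep from about 23:30 to 07:30 with a 30% deep-sleep fraction,
#' and a nocturnal heart-rate rhythm with mesor 62 bpm, amplitude 6 bpm and
#' acrophase 4 h (early-morning peak of the fitted 24-h cosine).
#'
#' @param participant_id opaque id string.
#' @param calls_per_day named rates for `incoming`, `outgoing`, `rejected`.
#' @param screen_sessions_per_day expected unlock count per day.
#' @param app_sessions_per_day named per-category session rates (the seven
#'   assignable categories of [APP_CATEGORIES]).
#' @param mean_daily_steps expected daily step total.
#' @param sleep_onset_hour,wake_hour clock hours; onset may exceed 24 is not
#'   allowed — use e.g. 23.5 for 23:30.
#' @param deep_sleep_frac fraction of sleep minutes typed deep, in `[0,1]`.
#' @param hr_mesor,hr_amplitude,hr_acrophase cosinor parameters of the
#'   sleeping heart rate (bpm, bpm, hours in `[0,24)`).
#' @param compliance named per-stream probabilities that a day yields data.
#' @param n_peers size of the caller pool.
#' @param seed integer seed for this participant's streams.
#' @return object of class `participant_profile`.
#' @export
participant_profile <- function(participant_id = "p001",
    calls_per_day = c(incoming = 2.5, outgoing = 2.2, rejected = 0.4),
    screen_sessions_per_day = 40,
    app_sessions_per_day = c(instant_messaging = 25, social_networking = 8,
                             shopping = 3, entertainment = 6, music = 4,
                             food_delivery = 1.5, others = 6),
    mean_daily_steps = 6000,
    sleep_onset_hour = 23.5, wake_hour = 7.5,
    deep_sleep_frac = 0.3,
    hr_mesor = 62, hr_amplitude = 6, hr_acrophase = 4,
    compliance = c(call = 0.9, screen = 0.95, app = 0.95, wristband = 0.85),
    n_peers = 15, seed = 1L) {
  p <- list(participant_id = participant_id,
            calls_per_day = calls_per_day,
            screen_sessions_per_day = screen_sessions_per_day,
            app_sessions_per_day = app_sessions_per_day,
            mean_daily_steps = mean_daily_steps,
            sleep_onset_hour = sleep_onset_hour, wake_hour = wake_hour,
            deep_sleep_frac = deep_sleep_frac,
            hr_mesor = hr_mesor, hr_amplitude = hr_amplitude,
            hr_acrophase = hr_acrophase,
            compliance = compliance, n_peers = n_peers,
            seed = as.integer(seed))
  rates <- c(p$calls_per_day, p$screen_sessions_per_day,
             p$app_sessions_per_day, p$mean_daily_steps)
  stopifnot(all(rates >= 0),
            p$deep_sleep_frac >= 0, p$deep_sleep_frac <= 1,
            p$hr_amplitude >= 0,
            p$hr_acrophase >= 0, p$hr_acrophase < 24,
            all(p$compliance >= 0 & p$compliance <= 1))
  class(p) <- "participant_profile"
  p
}

#' Construct a trajectory specification
#'
#' Describes the latent mood trajectory: the scenario (which study label the
#' PHQ-9 triple must earn), the submission times, and the multiplicative
#' behavioral shift applied after the middle submission for Swing scenarios.
#'
#' @param scenario one of `r paste(SCENARIOS, collapse = ", ")`.
#' @param phq9_times strictly increasing POSIXct submission times; default
#'   three submissions 14 days apart starting 2024-03-01, jittered by
#'   `jitter_hours`.
#' @param effect_size multiplicative factor applied to second-period
#'   behavioral rates for swing scenarios (calls, screen, apps, steps,
#'   deep-sleep fraction and HR amplitude are multiplied by it; total sleep
#'   time is stretched by `2 - effect_size`, i.e. hypersomnia under
#'   worsening).  Default 0.45 for `swing_drastic`, 0.7 for
#'   `swing_moderate`, 1 otherwise.
#' @param hr_noise_sd Gaussian noise SD of sleeping heart rate, bpm.
#' @param rate_cv day-to-day lognormal coefficient of variation of the
#'   behavioral rates.
#' @param jitter_hours uniform jitter (plus or minus) applied to the default
#'   submission times; the study protocol fixes only a roughly biweekly
#'   cadence with submission allowed at any time, so
#'   this is a free parameter.
#' @param start first submission time when `phq9_times` is NULL.
#' @return object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(scenario, phq9_times = NULL,
                            effect_size = NULL, hr_noise_sd = 2,
                            rate_cv = 0.15, jitter_hours = 12,
                            start = as.POSIXct("2024-03-01 09:00:00",
                                               tz = "UTC")) {
  if (!scenario %in% SCENARIOS)
    stop("invalid scenario name: ", scenario)
  if (is.null(phq9_times)) {
    phq9_times <- start + c(0, 14, 28) * 86400 +
      c(0, runif(2, -jitter_hours, jitter_hours) * 3600)
  }
  if (any(diff(as.numeric(phq9_times)) <= 0))
    stop("phq9_times must be strictly increasing")
  if (is.null(effect_size)) {
    effect_size <- switch(scenario, swing_drastic = 0.45,
                          swing_moderate = 0.7, 1)
  }
  s <- list(scenario = scenario, phq9_times = phq9_times,
            effect_size = effect_size, hr_noise_sd = hr_noise_sd,
            rate_cv = rate_cv)
  class(s) <- "trajectory_spec"
  s
}

# all 28^3 PHQ-9 triples with their label, memoized
.triple_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      g <- expand.grid(s1 = 0:27, s2 = 0:27, s3 = 0:27)
      g$label <- assign_label(g$s1, g$s2, g$s3)
      tab <<- g
    }
    tab
  }
})

# draw one PHQ-9 triple uniformly from the integer set earning the
# scenario's label under the labeling precedence; null_effect draws from
# the full cube
draw_scenario_scores <- function(scenario) {
  tab <- .triple_table()
  pool <- if (scenario == "null_effect") tab else tab[tab$label == scenario, ]
  i <- sample.int(nrow(pool), 1)
  as.integer(pool[i, c("s1", "s2", "s3")])
}

sample_clock_hours <- function(n, weights24) {
  if (n == 0) return(numeric(0))
  bin <- sample.int(24, n, replace = TRUE, prob = weights24) - 1
  bin + runif(n)
}

day_factor <- function(cv) {
  if (cv <= 0) return(1)
  s <- sqrt(log(1 + cv^2))
  exp(rnorm(1, -s^2 / 2, s))
}

# effect-adjusted copy of the baseline rates for the second period
apply_effect <- function(profile, e) {
  p <- profile
  p$calls_per_day <- profile$calls_per_day * e
  p$screen_sessions_per_day <- profile$screen_sessions_per_day * e
  p$app_sessions_per_day <- profile$app_sessions_per_day * e
  p$mean_daily_steps <- profile$mean_daily_steps * e
  p$deep_sleep_frac <- min(1, profile$deep_sleep_frac * e)
  p$hr_amplitude <- profile$hr_amplitude * e
  # worsening lengthens time in bed: stretch the sleep window
  dur <- (profile$wake_hour - profile$sleep_onset_hour) %% 24
  p$wake_hour <- (profile$sleep_onset_hour + dur * (2 - e)) %% 24
  p
}

#' Generate raw event streams for one participant
#'
#' Draws event times from inhomogeneous Poisson processes with clock-time
#' intensity profiles (calls and screen use by day, sleep by night),
#' wristband minute-packets at exactly one per minute, and PHQ-9 scores
#' satisfying the scenario's label criterion.  For swing scenarios the
#' behavioral rates after the middle PHQ-9 time are multiplied by
#' `spec$effect_size`.  Heart rate is emitted only for minutes typed light
#' or deep sleep and follows
#' \eqn{mesor + amplitude \cos(2\pi (t - acrophase)/24)} plus Gaussian
#' noise on the local clock hour \eqn{t}.
#'
#' @param profile a [participant_profile()].
#' @param spec a [trajectory_spec()].
#' @return list with `streams` (named list of data.frames `call`, `screen`,
#'   `app`, `wristband`) and `phq9` (data.frame `ts`, `score`).
#' @export
generate_participant <- function(profile, spec) {
  stopifnot(inherits(profile, "participant_profile"),
            inherits(spec, "trajectory_spec"))
  set.seed(profile$seed)
  t1 <- spec$phq9_times[1]
  t_mid <- spec$phq9_times[ceiling(length(spec$phq9_times) / 2)]
  t_end <- spec$phq9_times[length(spec$phq9_times)]
  scores <- draw_scenario_scores(spec$scenario)
  if (length(spec$phq9_times) > 3) {
    extra <- draw_scenario_scores(spec$scenario)
    scores <- c(scores, rep(extra, length.out = length(spec$phq9_times) - 3))
  }
  phq9 <- data.frame(ts = spec$phq9_times,
                     score = scores[seq_along(spec$phq9_times)])

  prof2 <- apply_effect(profile, spec$effect_size)
  days <- seq(as.POSIXct(trunc(t1, "days")), as.POSIXct(trunc(t_end, "days")),
              by = "1 day")

  calls <- list(); screens <- list(); apps <- list(); wrist <- list()
  for (d in seq_along(days)) {
    day <- days[d]
    pr <- if (day + 43200 < t_mid) profile else prof2
    calls[[d]]  <- gen_day_calls(pr, day, spec$rate_cv)
    screens[[d]] <- gen_day_screen(pr, day, spec$rate_cv)
    apps[[d]]   <- gen_day_apps(pr, day, spec$rate_cv)
    wrist[[d]]  <- gen_day_wristband(pr, day, spec)
  }
  wb <- clip_stream(do.call(rbind, wrist), "ts", t1, t_end)
  if (nrow2(wb)) wb <- wb[!duplicated(wb$ts), , drop = FALSE]  # night overlap
  streams <- list(
    call = clip_stream(do.call(rbind, calls), "ts", t1, t_end),
    screen = clip_stream(do.call(rbind, screens), "ts", t1, t_end),
    app = clip_stream(do.call(rbind, apps), "ts_start", t1, t_end),
    wristband = wb)
  list(streams = streams, phq9 = phq9)
}

clip_stream <- function(df, tcol, t1, t2) {
  if (is.null(df) || nrow(df) == 0) return(df)
  df <- df[df[[tcol]] >= t1 & df[[tcol]] < t2, , drop = FALSE]
  df[order(df[[tcol]]), , drop = FALSE]
}

gen_day_calls <- function(pr, day, cv) {
  empty <- data.frame(ts = as.POSIXct(character(), tz = "UTC"),
                      direction = character(), duration_s = numeric(),
                      peer = character())
  if (runif(1) > pr$compliance["call"]) return(empty)
  rate <- sum(pr$calls_per_day) * day_factor(cv)
  n <- rpois(1, rate)
  if (n == 0) return(empty)
  dirp <- pr$calls_per_day / sum(pr$calls_per_day)
  direction <- sample(names(dirp), n, replace = TRUE, prob = dirp)
  hours <- sample_clock_hours(n, .hour_profile$call)
  dur <- ifelse(direction == "rejected", 0,
                round(rlnorm(n, log(90), 0.9), 1))
  peer_w <- 1 / seq_len(pr$n_peers)  # few close contacts dominate
  peer <- sprintf("peer%02d",
                  sample.int(pr$n_peers, n, replace = TRUE, prob = peer_w))
  data.frame(ts = day + hours * 3600, direction = direction,
             duration_s = dur, peer = peer)
}

gen_day_screen <- function(pr, day, cv) {
  empty <- data.frame(ts = as.POSIXct(character(), tz = "UTC"),
                      event = character())
  if (runif(1) > pr$compliance["screen"]) return(empty)
  n <- rpois(1, pr$screen_sessions_per_day * day_factor(cv))
  if (n == 0) return(empty)
  start <- sort(day + sample_clock_hours(n, .hour_profile$screen) * 3600)
  dur <- round(rlnorm(n, log(150), 1.0))
  # drop sessions that would overlap their successor
  keep <- rep(TRUE, n); last_end <- -Inf
  for (i in seq_len(n)) {
    if (as.numeric(start[i]) < last_end) keep[i] <- FALSE
    else last_end <- as.numeric(start[i]) + dur[i]
  }
  start <- start[keep]; dur <- dur[keep]
  ts <- as.POSIXct(as.vector(rbind(as.numeric(start),
                                   as.numeric(start) + dur)),
                   origin = "1970-01-01", tz = "UTC")
  data.frame(ts = ts, event = rep(c("on", "off"), length(start)))
}

.app_dur_meanlog <- c(instant_messaging = log(60), social_networking = log(180),
                      shopping = log(240), entertainment = log(600),
                      music = log(900), food_delivery = log(120),
                      others = log(90))

gen_day_apps <- function(pr, day, cv) {
  empty <- data.frame(ts_start = as.POSIXct(character(), tz = "UTC"),
                      ts_end = as.POSIXct(character(), tz = "UTC"),
                      app_id = character(), category = character())
  if (runif(1) > pr$compliance["app"]) return(empty)
  f <- day_factor(cv)
  out <- lapply(APP_CATEGORIES, function(cat) {
    n <- rpois(1, pr$app_sessions_per_day[[cat]] * f)
    if (n == 0) return(NULL)
    start <- day + sample_clock_hours(n, .hour_profile$screen) * 3600
    dur <- round(rlnorm(n, .app_dur_meanlog[[cat]], 0.8))
    data.frame(ts_start = start, ts_end = start + dur,
               app_id = sprintf("%s_%02d", cat,
                                sample.int(3, n, replace = TRUE)),
               category = cat)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty else out
}

# minute-packet stream for one night + following day
gen_day_wristband <- function(pr, day, spec) {
  empty <- data.frame(ts = as.POSIXct(character(), tz = "UTC"),
                      type = character(), intensity = numeric(),
                      steps = integer(), heart_rate = numeric())
  if (runif(1) > pr$compliance["wristband"]) return(empty)
  onset_h <- pr$sleep_onset_hour + rnorm(1, 0, 0.5)
  dur_h <- ((pr$wake_hour - pr$sleep_onset_hour) %% 24) + rnorm(1, 0, 0.5)
  dur_h <- max(3, dur_h)
  onset <- day + round(onset_h * 60) * 60  # on the minute grid
  n_sleep <- round(dur_h * 60)
  sleep_ts <- onset + (seq_len(n_sleep) - 1) * 60
  sleep_type <- sleep_architecture(n_sleep, pr$deep_sleep_frac)
  h <- clock_hour(sleep_ts)
  hr <- pr$hr_mesor +
    pr$hr_amplitude * cos(2 * pi * (h - pr$hr_acrophase) / 24) +
    rnorm(n_sleep, 0, spec$hr_noise_sd)
  night <- data.frame(ts = sleep_ts, type = sleep_type, intensity = 0,
                      steps = 0L, heart_rate = hr)

  # waking minutes of this calendar day before onset and after last wake
  day_min <- day + (0:1439) * 60
  awake <- day_min[!(day_min %in% sleep_ts)]
  # previous night's tail also occupies the morning; approximate with the
  # same schedule: minutes before (onset_h - 24 + dur_h) are asleep
  wake_h <- (onset_h + dur_h) - 24
  if (wake_h > 0) awake <- awake[clock_hour(awake) >= wake_h]
  n_aw <- length(awake)
  if (n_aw == 0) return(night)
  type <- rep("activity", n_aw)
  # not-worn daytime gaps
  n_gap <- rpois(1, 1.2)
  for (g in seq_len(n_gap)) {
    gs <- sample.int(n_aw, 1); gl <- sample(30:150, 1)
    type[gs:min(n_aw, gs + gl)] <- "not_worn"
  }
  steps <- integer(n_aw)
  worn <- type == "activity"
  total <- rpois(1, pr$mean_daily_steps * day_factor(spec$rate_cv))
  if (any(worn) && total > 0) {
    w <- .hour_profile$steps[floor(clock_hour(awake[worn])) + 1]
    alloc <- as.integer(rmultinom(1, total, w))
    steps[worn] <- alloc
  }
  intensity <- ifelse(worn, round(pmin(steps, 120) / 2 + runif(n_aw, 0, 5), 1), 0)
  dayrec <- data.frame(ts = awake, type = type, intensity = intensity,
                       steps = steps, heart_rate = NA_real_)
  out <- rbind(night, dayrec)
  out[order(out$ts), ]
}

# light/deep minute types: ~90-min cycles, deep block early in each cycle
sleep_architecture <- function(n, deep_frac) {
  if (n == 0) return(character(0))
  cyc <- 90
  type <- rep("light_sleep", n)
  starts <- seq(1, n, by = cyc)
  for (s in starts) {
    len <- min(cyc, n - s + 1)
    nd <- round(len * deep_frac)
    if (nd > 0) {
      off <- sample.int(max(1, len - nd + 1), 1) - 1
      type[(s + off):(s + off + nd - 1)] <- "deep_sleep"
    }
  }
  type[seq_len(n)]
}

#' Generate and write a synthetic cohort
#'
#' Draws `n_per_scenario` participants for each scenario, randomizing
#' baseline profiles around the [participant_profile()] defaults, and writes
#' one directory per participant in the JSON-lines interchange schemas
#' (`calls.jsonl`, `screen.jsonl`, `apps.jsonl`, `wristband.jsonl`,
#' `phq9.jsonl`) plus a cohort `manifest.json`.  Byte-identical output under
#' a fixed seed.
#'
#' @param n_per_scenario participants per scenario (>= 1).
#' @param seed cohort seed; per-participant seeds are derived from it.
#' @param out_dir output directory (created if missing).
#' @param scenarios scenarios to include (default all five).
#' @param config optional list overriding generator knobs:
#'   `effect_drastic`, `effect_moderate`, `hr_noise_sd`, `rate_cv`,
#'   `jitter_hours`, `start`.
#' @return invisibly, the manifest data.frame.
#' @export
generate_cohort <- function(n_per_scenario, seed, out_dir,
                            scenarios = SCENARIOS, config = list()) {
  stopifnot(n_per_scenario >= 1)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  set.seed(seed)
  n_total <- n_per_scenario * length(scenarios)
  pseeds <- sample.int(.Machine$integer.max - 1L, n_total)
  cfg <- utils::modifyList(list(effect_drastic = 0.45, effect_moderate = 0.7,
                                hr_noise_sd = 2, rate_cv = 0.15,
                                jitter_hours = 12,
                                start = as.POSIXct("2024-03-01 09:00:00",
                                                   tz = "UTC")), config)
  manifest <- list(); idx <- 0
  for (sc in scenarios) {
    for (i in seq_len(n_per_scenario)) {
      idx <- idx + 1
      pid <- sprintf("p%03d", idx)
      set.seed(pseeds[idx])
      stream_seed <- sample.int(.Machine$integer.max - 1L, 1)
      profile <- randomize_profile(pid, stream_seed)
      eff <- switch(sc, swing_drastic = cfg$effect_drastic,
                    swing_moderate = cfg$effect_moderate, 1)
      spec <- trajectory_spec(sc, effect_size = eff,
                              hr_noise_sd = cfg$hr_noise_sd,
                              rate_cv = cfg$rate_cv,
                              jitter_hours = cfg$jitter_hours,
                              start = cfg$start)
      dat <- generate_participant(profile, spec)
      write_participant(file.path(out_dir, pid), dat)
      manifest[[idx]] <- data.frame(participant_id = pid, scenario = sc,
                                    seed = pseeds[idx],
                                    effect_size = spec$effect_size)
    }
  }
  manifest <- do.call(rbind, manifest)
  jsonlite::write_json(list(seed = seed, n_per_scenario = n_per_scenario,
                            participants = manifest),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

# per-participant heterogeneity around the defaults
randomize_profile <- function(pid, seed) {
  r <- function(x, cv = 0.3) x * exp(rnorm(length(x), 0, cv))
  participant_profile(
    participant_id = pid,
    calls_per_day = r(c(incoming = 2.5, outgoing = 2.2, rejected = 0.4)),
    screen_sessions_per_day = r(40),
    app_sessions_per_day = r(c(instant_messaging = 25, social_networking = 8,
                               shopping = 3, entertainment = 6, music = 4,
                               food_delivery = 1.5, others = 6)),
    mean_daily_steps = r(6000),
    sleep_onset_hour = (23.5 + rnorm(1, 0, 0.7)) %% 24,
    wake_hour = (7.5 + rnorm(1, 0, 0.7)) %% 24,
    deep_sleep_frac = min(0.6, max(0.1, rnorm(1, 0.3, 0.05))),
    hr_mesor = rnorm(1, 62, 4),
    hr_amplitude = max(1, rnorm(1, 6, 1.5)),
    hr_acrophase = (4 + rnorm(1, 0, 1)) %% 24,
    n_peers = sample(8:25, 1),
    seed = seed)
}

# ---- JSON-lines writers (deterministic formatting) ----

jesc <- function(x) gsub('"', '\\\\"', x)

write_jsonl <- function(lines, path) {
  con <- file(path, open = "wb")  # binary: LF endings on every platform
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con, sep = "\n")
  invisible(path)
}

num_or_null <- function(x) {
  ifelse(is.na(x), "null", formatC(x, format = "g", digits = 15))
}

write_participant <- function(dir, dat) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  s <- dat$streams
  write_jsonl(if (nrow2(s$call)) sprintf(
    '{"ts":"%s","direction":"%s","duration_s":%s,"peer":"%s"}',
    format_ts(s$call$ts), s$call$direction,
    num_or_null(s$call$duration_s), s$call$peer) else character(0),
    file.path(dir, "calls.jsonl"))
  write_jsonl(if (nrow2(s$screen)) sprintf(
    '{"ts":"%s","event":"%s"}', format_ts(s$screen$ts), s$screen$event)
    else character(0), file.path(dir, "screen.jsonl"))
  write_jsonl(if (nrow2(s$app)) sprintf(
    '{"ts_start":"%s","ts_end":"%s","app_id":"%s","category":"%s"}',
    format_ts(s$app$ts_start), format_ts(s$app$ts_end),
    s$app$app_id, s$app$category) else character(0),
    file.path(dir, "apps.jsonl"))
  write_jsonl(if (nrow2(s$wristband)) sprintf(
    '{"ts":"%s","type":"%s","intensity":%s,"steps":%d,"heart_rate":%s}',
    format_ts(s$wristband$ts), s$wristband$type,
    num_or_null(s$wristband$intensity), s$wristband$steps,
    num_or_null(s$wristband$heart_rate)) else character(0),
    file.path(dir, "wristband.jsonl"))
  write_jsonl(sprintf('{"ts":"%s","score":%d}',
                      format_ts(dat$phq9$ts), dat$phq9$score),
              file.path(dir, "phq9.jsonl"))
  invisible(dir)
}

nrow2 <- function(df) !is.null(df) && nrow(df) > 0
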