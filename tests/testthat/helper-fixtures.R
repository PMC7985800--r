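# shared fixtures, all built in code

ts_utc <- function(x) as.POSIXct(x, tz = "UTC")

# screen stream from alternating event spec
screen_stream <- function(times, events, id = "t") {
  moodstab:::new_event_stream(id, "screen",
                              data.frame(ts = ts_utc(times), event = events))
}

# call records data.frame
call_records <- function(times, direction, duration_s, peer) {
  data.frame(ts = ts_utc(times), direction = direction,
             duration_s = duration_s, peer = peer)
}

# wristband minute-packets: continuous run of a type starting at `from`
wb_run <- function(from, n_min, type, hr = NA_real_, steps = 0L) {
  ts <- ts_utc(from) + (seq_len(n_min) - 1) * 60
  data.frame(ts = ts, type = type, intensity = 0, steps = steps,
             heart_rate = hr)
}

# PHQ-9 data.frame from day offsets (relative to a fixed origin)
phq9_at <- function(day_offsets, scores,
                    origin = ts_utc("2024-03-01 09:00:00")) {
  data.frame(ts = origin + day_offsets * 86400, score = as.integer(scores))
}

default_period <- function(days = 14, origin = ts_utc("2024-03-01 00:00:00")) {
  c(origin, origin + days * 86400)
}

# cached small cohorts, generated once per test run
.cohort_cache <- new.env(parent = emptyenv())
cached_cohort <- function(key, n_per_scenario, seed, scenarios, config = list()) {
  if (is.null(.cohort_cache[[key]])) {
    d <- file.path(tempdir(), paste0("moodstab_", key))
    unlink(d, recursive = TRUE)
    generate_cohort(n_per_scenario, seed, d, scenarios = scenarios,
                    config = config)
    .cohort_cache[[key]] <- d
  }
  .cohort_cache[[key]]
}

# feature tables for cached cohorts, computed once
.tab_cache <- new.env(parent = emptyenv())
cached_table <- function(key, ...) {
  if (is.null(.tab_cache[[key]]))
    .tab_cache[[key]] <- build_feature_table(cached_cohort(key, ...))
  .tab_cache[[key]]
}
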