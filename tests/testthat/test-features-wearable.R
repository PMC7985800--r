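period14 <- default_period(14)

test_that("segment_nights: runs, bridging and the nap rule", {
  wb <- wb_run("2024-03-01 23:00:00", 480, "light_sleep", hr = 60)
  n1 <- segment_nights(wb, period14)
  expect_equal(nrow(n1), 1)
  expect_equal(n1$total_min, 480)
  expect_true(n1$valid)
  expect_equal(n1$onset, ts_utc("2024-03-01 23:00:00"))
  expect_equal(n1$wake, ts_utc("2024-03-02 07:00:00"))

  # two runs separated by 30 min merge under the 60-min bridge
  wb2 <- rbind(wb_run("2024-03-01 23:00:00", 180, "light_sleep", hr = 60),
               wb_run("2024-03-02 02:30:00", 270, "deep_sleep", hr = 58))
  n2 <- segment_nights(wb2, period14)
  expect_equal(nrow(n2), 1)
  expect_equal(n2$light_min, 180)
  expect_equal(n2$deep_min, 270)
  # but split under a 20-min bridge
  expect_equal(nrow(segment_nights(wb2, period14, bridge_min = 20)), 2)

  # a 90-min afternoon nap is not a valid night
  nap <- segment_nights(wb_run("2024-03-01 14:00:00", 90, "light_sleep",
                               hr = 65), period14)
  expect_false(any(nap$valid))
  expect_equal(unname(sleep_features(nap)["sleep.total_mean"]), NaN)
})

test_that("sleep features: ratios, degenerate n = 1, circular onset", {
  wb <- do.call(rbind, lapply(0:4, function(d)
    rbind(wb_run(ts_utc("2024-03-01 23:00:00") + d * 86400, 300,
                 "light_sleep", hr = 60),
          wb_run(ts_utc("2024-03-02 04:00:00") + d * 86400, 180,
                 "deep_sleep", hr = 58))))
  f <- sleep_features(segment_nights(wb, period14))
  expect_equal(unname(f["sleep.deep_ratio"]), 0.375)
  expect_equal(unname(f["sleep.light_ratio"]), 0.625)
  expect_equal(unname(f["sleep.total_sd"]), 0)
  expect_equal(unname(f["sleep.total_mean"]), 480)
  expect_equal(unname(f["sleep.onset_hour"]), 23)

  one <- sleep_features(segment_nights(
    wb_run("2024-03-01 23:00:00", 400, "light_sleep", hr = 60), period14))
  expect_true(is.nan(one["sleep.total_sd"]))
  expect_equal(unname(one["sleep.total_mean"]), 400)

  # onsets 23:30 and 00:30 -> circular mean midnight
  wb3 <- rbind(wb_run("2024-03-01 23:30:00", 400, "light_sleep", hr = 60),
               wb_run("2024-03-04 00:30:00", 400, "light_sleep", hr = 60))
  f3 <- sleep_features(segment_nights(wb3, period14))
  expect_equal(unname(f3["sleep.onset_hour"]), 0, tolerance = 1e-9)
})

test_that("step features: daily totals, bins, empty convention", {
  wb <- do.call(rbind, lapply(0:3, function(d)
    wb_run(ts_utc("2024-03-01 08:00:00") + d * 86400, 900, "activity",
           steps = 10L)))
  f <- step_features(wb, period14)
  expect_equal(unname(f["step.daily_mean"]), 9000)
  expect_equal(unname(f["step.daily_sd"]), 0)
  expect_equal(unname(f["step.total"]), 36000)

  wb2 <- wb_run("2024-03-01 09:00:00", 180, "activity", steps = 5L)
  f2 <- step_features(wb2, period14)
  expect_equal(unname(f2["step.09_12_mean"]), 900)
  expect_equal(unname(f2["step.00_03_mean"]), 0)
  expect_equal(unname(f2["step.total"]), 900)

  f3 <- step_features(NULL, period14)
  expect_equal(unname(f3["step.total"]), 0)
  expect_true(is.nan(f3["step.daily_mean"]))
  # not-worn packets carry no steps
  f4 <- step_features(wb_run("2024-03-01 09:00:00", 100, "not_worn",
                             steps = 3L), period14)
  expect_equal(unname(f4["step.total"]), 0)
})

test_that("cosinor: exact recovery, flat signal, minimum points", {
  ts <- ts_utc("2024-03-01 23:00:00") + (0:479) * 60
  h <- moodstab:::clock_hour(ts)
  y <- 60 + 10 * cos(2 * pi * (h - 4) / 24)
  f <- fit_cosinor(ts, y)
  expect_equal(f$mesor, 60, tolerance = 1e-6)
  expect_equal(f$amplitude, 10, tolerance = 1e-6)
  expect_equal(f$acrophase, 4, tolerance = 1e-6)
  expect_equal(f$r2, 1, tolerance = 1e-9)
  expect_equal(f$n_points, 480)

  flat <- fit_cosinor(ts, rep(55, 480))
  expect_equal(flat$mesor, 55)
  expect_equal(flat$amplitude, 0)
  expect_equal(flat$r2, 0)

  expect_null(fit_cosinor(ts[1:9], y[1:9]))
})

test_that("cosinor amplitude is recovered under noise within 3 SE", {
  set.seed(23)
  ts <- ts_utc("2024-03-01 22:00:00") + (0:399) * 60
  th <- (as.numeric(ts) - as.numeric(ts_utc("2024-03-01 00:00:00"))) / 3600
  h <- moodstab:::clock_hour(ts)
  sigma <- 2
  y <- 64 + 10 * cos(2 * pi * (h - 3) / 24) + rnorm(400, 0, sigma)
  f <- fit_cosinor(ts, y)
  # design-based SEs: a short sleep window makes the 24-h fit ill-conditioned,
  # so the naive sigma*sqrt(2/n) underestimates badly
  om <- 2 * pi / 24
  X <- cbind(1, cos(om * th), sin(om * th))
  Sigma <- sigma^2 * solve(crossprod(X))
  b_true <- c(10 * cos(om * 3), 10 * sin(om * 3))
  grad <- b_true / 10
  se_amp <- sqrt(drop(t(grad) %*% Sigma[2:3, 2:3] %*% grad))
  expect_lt(abs(f$amplitude - 10), 3 * se_amp)
  expect_lt(abs(f$mesor - 64), 3 * sqrt(Sigma[1, 1]))
})

test_that("heart-rate features summarize nightly fits", {
  wb <- do.call(rbind, lapply(0:3, function(d) {
    ts <- ts_utc("2024-03-01 23:00:00") + d * 86400 + (0:419) * 60
    h <- moodstab:::clock_hour(ts)
    data.frame(ts = ts, type = "light_sleep", intensity = 0, steps = 0L,
               heart_rate = 62 + 8 * cos(2 * pi * (h - 5) / 24))
  }))
  f <- heart_rate_features(wb, period14)
  expect_equal(unname(f["hr.n_fits"]), 4)
  expect_equal(unname(f["hr.mesor_mean"]), 62, tolerance = 1e-6)
  expect_equal(unname(f["hr.amplitude_sd"]), 0, tolerance = 1e-6)
  expect_equal(unname(f["hr.acrophase_mean"]), 5, tolerance = 1e-6)
  expect_equal(unname(f["hr.r2_mean"]), 1, tolerance = 1e-9)

  none <- heart_rate_features(NULL, period14,
                              nights = segment_nights(NULL, period14))
  expect_true(is.nan(none["hr.mesor_mean"]))
})

test_that("acrophase summaries are circular", {
  mk_night <- function(day, acro) {
    ts <- ts_utc("2024-03-01 23:00:00") + day * 86400 + (0:419) * 60
    h <- moodstab:::clock_hour(ts)
    data.frame(ts = ts, type = "deep_sleep", intensity = 0, steps = 0L,
               heart_rate = 60 + 6 * cos(2 * pi * (h - acro) / 24))
  }
  wb <- rbind(mk_night(0, 23), mk_night(1, 1))
  f <- heart_rate_features(wb, period14)
  expect_equal(unname(f["hr.acrophase_mean"]), 0, tolerance = 1e-6)
  expect_lt(unname(f["hr.acrophase_sd"]), 2.1)  # not the linear sd of 23 and 1
})

test_that("sleep minutes are conserved between nights and the raw stream", {
  d <- cached_cohort("tiny", 1, 101, "steady_remission")
  pd <- load_participant(file.path(d, "p001"))
  wb <- pd$streams$wristband$records
  period <- c(pd$phq9$ts[1], pd$phq9$ts[3])
  nights <- segment_nights(wb, period)
  in_p <- wb$ts >= period[1] & wb$ts < period[2]
  expect_equal(sum(nights$light_min) + sum(nights$deep_min),
               sum(wb$type[in_p] %in% c("light_sleep", "deep_sleep")))
})
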