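period14 <- default_period(14)

test_that("call features on empty, single-peer and duration examples", {
  f0 <- call_features(NULL, period14)
  expect_equal(unname(f0["call.all.count"]), 0)
  expect_true(is.nan(f0["call.all.peer_entropy"]))
  expect_true(is.nan(f0["call.incoming.mean_duration"]))

  f1 <- call_features(call_records(
    paste0("2024-03-0", 1:3, " 10:00:00"), "outgoing", c(30, 60, 90),
    "peer01"), period14)
  expect_equal(unname(f1["call.outgoing.distinct_peers"]), 1)
  expect_equal(unname(f1["call.outgoing.peer_entropy"]), 0)
  expect_equal(unname(f1["call.outgoing.count"]), 3)
  expect_equal(unname(f1["call.rejected.count"]), 0)
  expect_true(is.nan(f1["call.rejected.total_duration"]))

  f2 <- call_features(call_records(
    c("2024-03-01 10:00:00", "2024-03-02 10:00:00"), "incoming",
    c(60, 120), c("a", "b")), period14)
  expect_equal(unname(f2["call.incoming.mean_duration"]), 90)
  expect_equal(unname(f2["call.incoming.peer_entropy"]), 1)
  expect_equal(unname(f2["call.all.hour_mean"]), 10)
})

test_that("screen features: bins, sessions, per-day statistics", {
  one_day <- default_period(1)
  s <- screen_stream(c("2024-03-01 10:00:00", "2024-03-01 10:30:00"),
                     c("on", "off"))
  f <- screen_features(s$records, one_day)
  expect_equal(unname(f["screen.morning_ratio"]), 1)
  expect_equal(unname(f["screen.afternoon_ratio"]), 0)
  expect_equal(unname(f["screen.night_ratio"]), 0)

  # sessions of 10, 20, 30 minutes on three days
  times <- c("2024-03-01 09:00:00", "2024-03-01 09:10:00",
             "2024-03-02 09:00:00", "2024-03-02 09:20:00",
             "2024-03-03 09:00:00", "2024-03-03 09:30:00")
  f2 <- screen_features(screen_stream(times, rep(c("on", "off"), 3))$records,
                        period14)
  expect_equal(unname(f2["screen.session_duration_mean"]), 20 * 60)
  expect_equal(unname(f2["screen.daily_duration_mean"]), 20 * 60)
  expect_equal(unname(f2["screen.daily_duration_median"]), 20 * 60)
  expect_equal(unname(f2["screen.daily_count_mean"]), 1)

  # session spanning noon is split proportionally
  f3 <- screen_features(screen_stream(
    c("2024-03-01 11:30:00", "2024-03-01 12:30:00"), c("on", "off"))$records,
    one_day)
  expect_equal(unname(f3["screen.morning_ratio"]), 0.5)
  expect_equal(unname(f3["screen.afternoon_ratio"]), 0.5)

  f4 <- screen_features(NULL, period14)
  expect_true(is.nan(f4["screen.morning_ratio"]))
})

mk_apps <- function(starts, durs_s, cats) {
  data.frame(ts_start = ts_utc(starts), ts_end = ts_utc(starts) + durs_s,
             app_id = paste0(cats, "_01"), category = cats)
}

test_that("app features: ratios, entropies and bin splitting", {
  a <- mk_apps(rep("2024-03-01 10:00:00", 3), c(60, 120, 180),
               rep("instant_messaging", 3))
  f <- app_features(a, period14)
  expect_equal(unname(f["app.im_ratio"]), 1)
  expect_equal(unname(f["app.category_entropy_count"]), 0)
  expect_equal(unname(f["app.instant_messaging.count"]), 3)
  expect_equal(unname(f["app.all.duration_mean"]), 120)

  cats4 <- c("instant_messaging", "shopping", "music", "others")
  f2 <- app_features(mk_apps(rep("2024-03-01 10:00:00", 4), rep(300, 4),
                             cats4), period14)
  expect_equal(unname(f2["app.category_entropy_duration"]), 2)
  expect_equal(unname(f2["app.category_entropy_count"]), 2)
  expect_equal(unname(f2["app.im_ratio"]), 0.25)

  # session 02:50-03:10 splits 10 min / 10 min across the 3 AM boundary
  f3 <- app_features(mk_apps("2024-03-01 02:50:00", 1200, "others"), period14)
  expect_equal(unname(f3["app.others.duration_00_03"]), 600)
  expect_equal(unname(f3["app.others.duration_03_06"]), 600)
  expect_equal(unname(f3["app.others.count_00_03"]), 1)  # counted at start
})

test_that("bin durations conserve total duration", {
  set.seed(17)
  for (i in 1:25) {
    n <- sample(1:15, 1)
    starts <- ts_utc("2024-03-01 00:00:00") + runif(n, 0, 13 * 86400)
    durs <- runif(n, 10, 7200)
    a <- data.frame(ts_start = starts, ts_end = starts + durs,
                    app_id = "x_01", category = "others")
    f <- app_features(a, period14)
    bins <- f[sprintf("app.others.duration_%s", moodstab:::BIN_NAMES)]
    expect_equal(unname(sum(bins)), sum(durs), tolerance = 1e-8)
    expect_equal(unname(f["app.others.count"]), n)
  }
})

test_that("aggregate_periods identities and NaN propagation", {
  expect_equal(unname(aggregate_periods(c(x = 2), c(x = 2))),
               c(0, 2, 0))
  agg <- aggregate_periods(c(x = 1), c(x = 3))
  expect_equal(unname(agg["x.diff"]), 2)
  expect_equal(unname(agg["x.mean"]), 2)
  expect_equal(unname(agg["x.sd"]), sqrt(2))
  expect_equal(unname(agg["x.sd"]), stats::sd(c(1, 3)))  # n-1 convention

  nan <- aggregate_periods(c(x = NaN, y = 1), c(x = 3, y = 2))
  expect_true(all(is.nan(nan[c("x.diff", "x.mean", "x.sd")])))
  expect_false(anyNA(nan[c("y.diff", "y.mean", "y.sd")]))
  expect_error(aggregate_periods(c(x = 1), c(z = 1)), "name sets")
})

test_that("sd equals |diff|/sqrt(2) for all finite features", {
  set.seed(19)
  for (i in 1:20) {
    pf1 <- stats::setNames(rnorm(10), paste0("f", 1:10))
    pf2 <- stats::setNames(rnorm(10), paste0("f", 1:10))
    agg <- aggregate_periods(pf1, pf2)
    expect_equal(unname(agg[paste0("f", 1:10, ".sd")]),
                 unname(abs(agg[paste0("f", 1:10, ".diff")]) / sqrt(2)))
  }
})
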