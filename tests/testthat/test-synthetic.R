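test_that("fixed seed gives byte-identical cohorts", {
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  unlink(c(d1, d2), recursive = TRUE)
  generate_cohort(2, 7, d1, scenarios = c("steady_remission", "swing_drastic"))
  generate_cohort(2, 7, d2, scenarios = c("steady_remission", "swing_drastic"))
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_identical(f1, f2)
  h1 <- tools::md5sum(file.path(d1, f1))
  h2 <- tools::md5sum(file.path(d2, f2))
  expect_identical(unname(h1), unname(h2))
})

test_that("scenario scores satisfy their label criterion", {
  d <- cached_cohort("drastic5", 5, 21, "swing_drastic")
  for (p in sprintf("p%03d", 1:5)) {
    sc <- load_participant(file.path(d, p))$phq9$score
    expect_gte(max(sc) - min(sc), 10)
  }
  rem <- load_participant(file.path(cached_cohort("tiny", 1, 101,
                                                  "steady_remission"),
                                    "p001"))$phq9$score
  expect_true(all(rem <= 5))
})

test_that("zero compliance yields empty streams but PHQ-9 records remain", {
  prof <- participant_profile(compliance = c(call = 0, screen = 0, app = 0,
                                             wristband = 0), seed = 3)
  set.seed(3)
  dat <- generate_participant(prof, trajectory_spec("steady_depressed"))
  for (k in names(dat$streams)) expect_equal(nrow(dat$streams[[k]]), 0)
  expect_equal(nrow(dat$phq9), 3)
  expect_true(all(dat$phq9$score >= 11))
})

test_that("invalid scenario and non-increasing times are rejected", {
  expect_error(trajectory_spec("mildly_vexed"), "scenario")
  expect_error(trajectory_spec("null_effect",
                               phq9_times = ts_utc("2024-03-01") + c(0, 5, 5)),
               "increasing")
})

test_that("wristband packets keep minute cadence and sleep-only heart rate", {
  d <- cached_cohort("tiny", 1, 101, "steady_remission")
  wb <- load_participant(file.path(d, "p001"))$streams$wristband$records
  dd <- diff(as.numeric(wb$ts))
  expect_true(all(dd >= 60))
  expect_true(all(dd %% 60 == 0))
  expect_true(all(is.na(wb$heart_rate) |
                    wb$type %in% c("light_sleep", "deep_sleep")))
  expect_true(all(!is.na(wb$heart_rate[wb$type %in% c("light_sleep",
                                                      "deep_sleep")])))
  expect_true(any(wb$type == "not_worn"))  # daytime gaps exercised
})

test_that("noiseless generator nights recover the cosinor exactly", {
  prof <- participant_profile(hr_mesor = 60, hr_amplitude = 10,
                              hr_acrophase = 4, seed = 5)
  set.seed(5)
  spec <- trajectory_spec("steady_remission", hr_noise_sd = 0)
  dat <- generate_participant(prof, spec)
  wb <- dat$streams$wristband
  period <- c(spec$phq9_times[1], spec$phq9_times[3])
  nights <- segment_nights(wb, period)
  fits <- moodstab:::cosinor_by_night(wb, nights)
  expect_gt(length(fits), 5)
  for (f in fits) {
    expect_equal(f$mesor, 60, tolerance = 1e-6)
    expect_equal(f$amplitude, 10, tolerance = 1e-6)
    expect_equal(f$acrophase, 4, tolerance = 1e-6)
    expect_equal(f$r2, 1, tolerance = 1e-9)
  }
})

test_that("null_effect applies no behavioral shift", {
  spec <- trajectory_spec("null_effect")
  expect_equal(spec$effect_size, 1)
  prof <- participant_profile(seed = 9)
  shifted <- moodstab:::apply_effect(prof, 1)
  expect_equal(shifted$calls_per_day, prof$calls_per_day)
  expect_equal(shifted$mean_daily_steps, prof$mean_daily_steps)
  expect_equal(shifted$wake_hour, prof$wake_hour)
})

test_that("generated cohorts recover the intended label downstream", {
  for (sc in c("steady_remission", "steady_depressed",
               "swing_drastic", "swing_moderate")) {
    d <- cached_cohort(paste0("lab_", sc), 1, 31, sc)
    pd <- load_participant(file.path(d, "p001"))
    smp <- build_samples(pd$streams, pd$phq9, "p001")
    expect_equal(nrow(smp), 1)
    expect_equal(smp$label, sc)
  }
})
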