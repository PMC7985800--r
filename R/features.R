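# Sample-level feature assembly: per-period batteries -> diff/mean/sd
# aggregation -> cohort feature table with manifest.

# data-type combinations mirrored from the study's six experiments
DATA_COMBOS <- list(
  phone = list(prefixes = c("call", "screen", "app"),
               streams = c("call", "screen", "app")),
  sleep = list(prefixes = "sleep", streams = "wristband"),
  steps = list(prefixes = "step", streams = "wristband"),
  heart_rate = list(prefixes = "hr", streams = "wristband"),
  all = list(prefixes = c("call", "screen", "app", "sleep", "step", "hr"),
             streams = c("call", "screen", "app", "wristband")),
  call_sleep_steps_hr = list(prefixes = c("call", "sleep", "step", "hr"),
                             streams = c("call", "wristband")))

#' Compute the full per-period feature battery
#'
#' Runs every feature extractor (calls, screen, apps, sleep, steps, heart
#' rate) on one period of one participant's streams and concatenates the
#' results.
#'
#' @param streams named list of `event_stream`s (`call`, `screen`, `app`,
#'   `wristband`).
#' @param period POSIXct length-2 `[start, end)`.
#' @param config optional list: `bridge_min`, `min_night_min` for
#'   [segment_nights()].
#' @return named numeric vector of period features.
#' @export
period_features <- function(streams, period, config = list()) {
  bridge <- config$bridge_min %||% 60
  min_night <- config$min_night_min %||% 180
  wb <- streams$wristband$records
  nights <- segment_nights(wb, period, bridge, min_night)
  c(call_features(streams$call$records, period),
    screen_features(streams$screen$records, period),
    app_features(streams$app$records, period),
    sleep_features(nights),
    step_features(wb, period),
    heart_rate_features(wb, period, nights = nights))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compute sample feature vectors for one participant
#'
#' For each retained sample (row of [build_samples()] output) computes the
#' per-period batteries on `[t1, t2)` and `[t2, t3)` and aggregates them
#' with [aggregate_periods()].
#'
#' @param streams named list of `event_stream`s.
#' @param samples data.frame of samples (columns `t1`, `t2`, `t3`).
#' @param config see [period_features()].
#' @return numeric matrix, one row per sample, columns
#'   `<feature>.diff|mean|sd`.
#' @export
sample_features <- function(streams, samples, config = list()) {
  rows <- lapply(seq_len(nrow(samples)), function(i) {
    pf1 <- period_features(streams, c(samples$t1[i], samples$t2[i]), config)
    pf2 <- period_features(streams, c(samples$t2[i], samples$t3[i]), config)
    aggregate_periods(pf1, pf2)
  })
  do.call(rbind, rows)
}

#' Build the labeled sample table and feature matrix for a cohort directory
#'
#' Loads every participant directory under `dir` (any directory containing
#' `phq9.jsonl`), forms candidate samples, applies the period-length
#' discard, records per-stream effective-day counts, and computes the full
#' feature matrix.
#'
#' @param dir cohort directory as written by [generate_cohort()].
#' @param config optional list passed through: `min_period_days`,
#'   `min_events`, `min_worn_minutes`, `bridge_min`, `min_night_min`, `tz`.
#' @return list with `samples` (data.frame), `features` (matrix, rows
#'   aligned with `samples`), and `manifest` (data.frame naming every
#'   feature column).
#' @export
build_feature_table <- function(dir, config = list()) {
  dirs <- list.dirs(dir, recursive = FALSE)
  dirs <- dirs[file.exists(file.path(dirs, "phq9.jsonl"))]
  if (length(dirs) == 0) stop("no participant directories under ", dir)
  all_s <- list(); all_f <- list()
  for (d in dirs) {
    pd <- load_participant(d, tz = config$tz %||% "UTC")
    smp <- build_samples(pd$streams, pd$phq9, basename(d),
                         min_period_days = config$min_period_days %||% 7,
                         min_events = config$min_events %||% 1,
                         min_worn_minutes = config$min_worn_minutes %||% 240)
    if (nrow(smp) == 0) next
    ft <- sample_features(pd$streams, smp, config)
    all_s[[d]] <- smp; all_f[[d]] <- ft
  }
  samples <- do.call(rbind, all_s)
  rownames(samples) <- NULL
  features <- do.call(rbind, all_f)
  rownames(features) <- NULL
  list(samples = samples, features = features,
       manifest = feature_manifest(colnames(features)))
}

#' Describe feature columns
#'
#' @param names character vector of feature column names.
#' @return data.frame with `name`, `stream`, `base`, `aggregate`.
#' @export
feature_manifest <- function(names) {
  stream <- sub("\\..*$", "", names)
  agg <- sub("^.*\\.", "", names)
  base <- sub("\\.(diff|mean|sd)$", "", names)
  data.frame(name = names, stream = stream, base = base, aggregate = agg,
             stringsAsFactors = FALSE)
}

#' Filter samples and features for one data-type combination
#'
#' A sample enters a combination only if every stream the combination
#' relies on has at least `min_eff_days` effective days in both periods —
#' the per-combination discard that makes sample counts differ across the
#' six experiments.
#'
#' @param tab output of [build_feature_table()].
#' @param combo one of `r paste(names(DATA_COMBOS), collapse = ", ")`.
#' @param min_eff_days threshold (default 3).
#' @return list with filtered `samples` and `features` (columns restricted
#'   to the combination's prefixes).
#' @export
combo_subset <- function(tab, combo, min_eff_days = 3) {
  spec <- DATA_COMBOS[[combo]]
  if (is.null(spec)) stop("unknown data combo: ", combo)
  keep <- rep(TRUE, nrow(tab$samples))
  for (st in spec$streams) {
    keep <- keep &
      tab$samples[[paste0("eff_", st, "_p1")]] >= min_eff_days &
      tab$samples[[paste0("eff_", st, "_p2")]] >= min_eff_days
  }
  pref <- sub("\\..*$", "", colnames(tab$features))
  cols <- pref %in% spec$prefixes
  list(samples = tab$samples[keep, , drop = FALSE],
       features = tab$features[keep, cols, drop = FALSE])
}
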