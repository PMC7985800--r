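# Classifier benchmark: stratified k-fold CV over the experiment grid of
# data-type combinations x classification tasks x classifiers.
#
# Per-fold pipeline: impute (training-fold medians) -> standardize
# (training-fold center/scale) -> select (training fold only) -> fit.
# Accuracy is correct predictions over all predictions; recall is
# positive-class (Swing-side) recall: true positives over actual positives.

# the five classification tasks; positive class is always the Swing side
BENCH_TASKS <- list(
  steady_vs_swing = list(
    negative = c("steady_remission", "steady_depressed"),
    positive = c("swing_drastic", "swing_moderate")),
  remission_vs_drastic = list(negative = "steady_remission",
                              positive = "swing_drastic"),
  remission_vs_moderate = list(negative = "steady_remission",
                               positive = "swing_moderate"),
  depressed_vs_drastic = list(negative = "steady_depressed",
                              positive = "swing_drastic"),
  depressed_vs_moderate = list(negative = "steady_depressed",
                               positive = "swing_moderate"))

# training-fold imputation/standardization parameters
preproc_fit <- function(X) {
  med <- apply(X, 2, function(c) {
    m <- stats::median(c[is.finite(c)])
    if (is.finite(m)) m else 0
  })
  Xi <- X
  for (j in seq_len(ncol(X))) Xi[!is.finite(Xi[, j]), j] <- med[j]
  ctr <- colMeans(Xi)
  scl <- apply(Xi, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(median = med, center = ctr, scale = scl)
}

preproc_apply <- function(X, pp) {
  for (j in seq_len(ncol(X))) X[!is.finite(X[, j]), j] <- pp$median[j]
  scale(X, center = pp$center, scale = pp$scale)
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  fold
}

#' Stratified k-fold cross-validation of one classifier
#'
#' Runs the leakage-free pipeline (impute, standardize, select, fit — all
#' fit on the training fold only) and returns per-fold accuracy and
#' positive-class recall.  If the smaller class has fewer than `k` members
#' the fold count is reduced with a warning, never silently.
#'
#' @param X numeric feature matrix (may contain NaN; imputed per fold).
#' @param y two-level factor; the second level is the positive class.
#' @param model classifier name (see [ML_MODELS]).
#' @param k requested folds (default 10).
#' @param seed RNG seed for fold assignment and stochastic fits.
#' @param selection selection method: `"none"`, `"l1"` or `"tree"`.
#' @param sel_params list passed to the selector (`l1_strength`,
#'   `tree_threshold`, `ntree`).
#' @param model_params list passed to [fit_classifier()].
#' @return list: `accuracy` and `recall` (per-fold vectors, percent),
#'   `k` (folds actually used), `n_selected` (selection size on the full
#'   data set, the single number the report quotes).
#' @export
run_cv <- function(X, y, model, k = 10, seed = 1L, selection = "l1",
                   sel_params = list(), model_params = list()) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop("cross-validation needs two classes")
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  min_class <- min(table(y))
  if (min_class < k) {
    warning(sprintf("class with %d members < %d folds; reducing k to %d",
                    min_class, k, min_class))
    k <- min_class
  }
  if (k < 2) stop("need at least 2 members per class for CV")
  set.seed(seed)
  fold <- stratified_folds(y, k)
  pos <- levels(y)[2]
  acc <- rec <- numeric(k)
  for (f in seq_len(k)) {
    tr <- fold != f; te <- !tr
    pp <- preproc_fit(X[tr, , drop = FALSE])
    Xtr <- preproc_apply(X[tr, , drop = FALSE], pp)
    Xte <- preproc_apply(X[te, , drop = FALSE], pp)
    sel <- run_selection(selection, Xtr, y[tr], sel_params, seed)
    cols <- sel$selected
    if (length(cols) == 0) cols <- colnames(Xtr)  # selector found nothing
    m <- fit_classifier(model, Xtr[, cols, drop = FALSE], y[tr],
                        model_params)
    pred <- predict(m, Xte[, cols, drop = FALSE])
    truth <- y[te]
    acc[f] <- 100 * mean(pred == truth)
    rec[f] <- 100 * mean(pred[truth == pos] == pos)
  }
  # reported selection size: selection on the full (imputed) data set
  pp <- preproc_fit(X)
  sel_full <- run_selection(selection, preproc_apply(X, pp), y,
                            sel_params, seed)
  list(accuracy = acc, recall = rec, k = k,
       n_selected = length(sel_full$selected))
}

task_data <- function(combo_tab, task) {
  t <- BENCH_TASKS[[task]]
  lab <- combo_tab$samples$label
  keep <- lab %in% c(t$negative, t$positive)
  y <- factor(ifelse(lab[keep] %in% t$positive, "swing", "steady"),
              levels = c("steady", "swing"))
  list(X = combo_tab$features[keep, , drop = FALSE], y = y)
}

#' Run the full experiment grid
#'
#' Benchmarks every classifier on every task for every data-type
#' combination, mirroring the study's report format: per cell the class
#' sizes, the number of features selected, mean/SD accuracy and mean/SD
#' positive-class recall over folds, and the best model (highest mean
#' accuracy, ties broken alphabetically).
#'
#' @param tab output of [build_feature_table()].
#' @param config list: `combos`, `tasks`, `models`, `k`, `seed`,
#'   `selection`, `sel_params`, `model_params`, `min_eff_days`.
#' @return object of class `bench_report`: list with `cells` (long
#'   data.frame, one row per combo x task x model) and `best` (one row per
#'   combo x task, the table the study prints).
#' @export
run_grid <- function(tab, config = list()) {
  combos <- config$combos %||% names(DATA_COMBOS)
  tasks <- config$tasks %||% names(BENCH_TASKS)
  models <- config$models %||% ML_MODELS
  k <- config$k %||% 10
  seed <- config$seed %||% 1L
  selection <- config$selection %||% "l1"
  cells <- list()
  for (cb in combos) {
    sub <- combo_subset(tab, cb, config$min_eff_days %||% 3)
    for (tk in tasks) {
      td <- task_data(sub, tk)
      n_neg <- sum(td$y == "steady"); n_pos <- sum(td$y == "swing")
      for (md in models) {
        row <- data.frame(combo = cb, task = tk, model = md,
                          n_steady = n_neg, n_swing = n_pos,
                          n_selected = NA_integer_, k = NA_integer_,
                          acc_mean = NaN, acc_sd = NaN,
                          rec_mean = NaN, rec_sd = NaN,
                          stringsAsFactors = FALSE)
        if (min(n_neg, n_pos) >= 2) {
          cv <- withCallingHandlers(
            run_cv(td$X, td$y, md, k = k, seed = seed,
                   selection = selection,
                   sel_params = config$sel_params %||% list(),
                   model_params = config$model_params %||% list()),
            warning = function(w) invokeRestart("muffleWarning"))
          row$n_selected <- cv$n_selected
          row$k <- cv$k
          row$acc_mean <- mean(cv$accuracy)
          row$acc_sd <- stats::sd(cv$accuracy)
          row$rec_mean <- mean(cv$recall)
          row$rec_sd <- stats::sd(cv$recall)
        }
        cells[[length(cells) + 1]] <- row
      }
    }
  }
  cells <- do.call(rbind, cells)
  best <- do.call(rbind, lapply(split(cells, cells[c("combo", "task")],
                                      drop = TRUE), function(g) {
    g <- g[order(-g$acc_mean, g$model), , drop = FALSE]
    g[1, , drop = FALSE]
  }))
  rownames(best) <- NULL
  best <- best[order(match(best$combo, combos), match(best$task, tasks)), ]
  structure(list(cells = cells, best = best,
                 config = list(combos = combos, tasks = tasks,
                               models = models, k = k, seed = seed,
                               selection = selection)),
            class = "bench_report")
}

#' @export
print.bench_report <- function(x, ...) {
  cat("Benchmark report (", nrow(x$best), " cells; best model per cell)\n\n",
      sep = "")
  b <- x$best
  cat(sprintf("%-20s %-22s %4s %4s %4s %-14s %16s %16s\n",
              "combo", "task", "nS", "nW", "sel", "best model",
              "accuracy (SD)", "recall (SD)"))
  for (i in seq_len(nrow(b)))
    cat(sprintf("%-20s %-22s %4d %4d %4s %-14s %7.2f (%5.2f) %7.2f (%5.2f)\n",
                b$combo[i], b$task[i], b$n_steady[i], b$n_swing[i],
                ifelse(is.na(b$n_selected[i]), "-",
                       as.character(b$n_selected[i])),
                b$model[i], b$acc_mean[i], b$acc_sd[i],
                b$rec_mean[i], b$rec_sd[i]))
  invisible(x)
}

#' Permutation null of the best-model CV accuracy
#'
#' Re-runs the same best-model-over-`models` CV statistic on
#' `n_perm` label-shuffled copies of the data, yielding the null
#' distribution against which an observed accuracy can be compared (e.g.
#' its 95th percentile).
#'
#' @param X feature matrix.
#' @param y two-level factor.
#' @param models classifier names entering the max.
#' @param k folds.
#' @param n_perm number of label shuffles (default 200).
#' @param seed RNG seed.
#' @param selection,sel_params see [run_cv()].
#' @return list: `observed` (best mean accuracy on the real labels),
#'   `null` (vector of n_perm best mean accuracies under shuffling).
#' @export
perm_null_accuracy <- function(X, y, models = c("logistic", "naive_bayes",
                                                "knn"),
                               k = 5, n_perm = 200, seed = 1L,
                               selection = "l1", sel_params = list()) {
  best_acc <- function(yy, s) {
    max(vapply(models, function(md)
      mean(suppressWarnings(
        run_cv(X, yy, md, k = k, seed = s, selection = selection,
               sel_params = sel_params))$accuracy), 0))
  }
  observed <- best_acc(y, seed)
  set.seed(seed)
  perm_seeds <- sample.int(.Machine$integer.max - 1L, n_perm)
  null <- vapply(seq_len(n_perm), function(i) {
    set.seed(perm_seeds[i])
    best_acc(sample(y), perm_seeds[i])
  }, 0)
  list(observed = observed, null = null)
}
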