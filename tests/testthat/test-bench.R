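test_that("separable labels give 100% accuracy with zero SD", {
  set.seed(67)
  n <- 60
  y <- factor(rep(c("steady", "swing"), each = n / 2),
              levels = c("steady", "swing"))
  X <- cbind(sig = ifelse(y == "swing", 5, -5) + rnorm(n, 0, 0.01),
             noise = rnorm(n))
  cv <- run_cv(X, y, "logistic", k = 10, seed = 1, selection = "none")
  expect_equal(mean(cv$accuracy), 100)
  expect_equal(stats::sd(cv$accuracy), 0)
  expect_equal(mean(cv$recall), 100)
})

test_that("random balanced labels give chance accuracy within binomial error", {
  set.seed(71)
  n <- 200
  y <- factor(sample(rep(c("steady", "swing"), n / 2)),
              levels = c("steady", "swing"))
  X <- matrix(rnorm(n * 5), n, 5)
  colnames(X) <- paste0("f", 1:5)
  cv <- run_cv(X, y, "logistic", k = 10, seed = 2, selection = "none")
  se <- 100 * sqrt(0.25 / n)  # binomial SE of the pooled accuracy
  expect_lt(abs(mean(cv$accuracy) - 50), 3 * se + 1e-9)
})

test_that("degenerate and small-class inputs follow the CV contract", {
  X <- matrix(rnorm(40), 20, 2)
  expect_error(run_cv(X, factor(rep("swing", 20)), "logistic"),
               "two classes")
  y <- factor(c(rep("steady", 4), rep("swing", 16)),
              levels = c("steady", "swing"))
  expect_warning(cv <- run_cv(X, y, "logistic", k = 10, selection = "none"),
                 "reducing k")
  expect_equal(cv$k, 4)
})

test_that("stratified folds preserve class ratios within one sample", {
  set.seed(73)
  y <- factor(c(rep("steady", 30), rep("swing", 60)))
  fold <- moodstab:::stratified_folds(y, 10)
  for (f in 1:10) {
    expect_equal(sum(fold == f & y == "steady"), 3)
    expect_equal(sum(fold == f & y == "swing"), 6)
  }
})

test_that("run_cv is deterministic under a fixed seed", {
  set.seed(79)
  y <- factor(rep(c("steady", "swing"), 20), levels = c("steady", "swing"))
  X <- matrix(rnorm(40 * 6), 40, 6)
  colnames(X) <- paste0("f", 1:6)
  a <- run_cv(X, y, "random_forest", k = 5, seed = 5, selection = "l1",
              model_params = list(ntree = 20))
  b <- run_cv(X, y, "random_forest", k = 5, seed = 5, selection = "l1",
              model_params = list(ntree = 20))
  expect_identical(a, b)
})

test_that("NaN features are imputed inside folds, not globally", {
  set.seed(83)
  y <- factor(rep(c("steady", "swing"), 25), levels = c("steady", "swing"))
  X <- matrix(rnorm(50 * 3), 50, 3)
  X[sample(150, 30)] <- NaN
  colnames(X) <- paste0("f", 1:3)
  cv <- run_cv(X, y, "naive_bayes", k = 5, seed = 6, selection = "none")
  expect_true(all(is.finite(cv$accuracy)))
})

test_that("run_grid reports the full grid with best-model rows", {
  tab <- cached_table("grid", 2, 91,
                      c("steady_remission", "steady_depressed",
                        "swing_drastic", "swing_moderate"))
  cfg <- list(combos = c("sleep", "steps"), tasks = "steady_vs_swing",
              models = c("logistic", "naive_bayes"), k = 3, seed = 4,
              selection = "l1")
  rep <- run_grid(tab, cfg)
  expect_s3_class(rep, "bench_report")
  expect_equal(nrow(rep$cells), 2 * 1 * 2)
  expect_equal(nrow(rep$best), 2)
  expect_true(all(rep$cells$acc_mean >= 0 & rep$cells$acc_mean <= 100,
                  na.rm = TRUE))
  expect_true(all(rep$cells$acc_sd >= 0, na.rm = TRUE))
  # best = argmax mean accuracy within each combo x task
  for (i in seq_len(nrow(rep$best))) {
    g <- rep$cells[rep$cells$combo == rep$best$combo[i], ]
    expect_equal(rep$best$acc_mean[i], max(g$acc_mean))
  }
  # determinism of the whole grid
  rep2 <- run_grid(tab, cfg)
  expect_identical(rep$cells, rep2$cells)
  expect_output(print(rep), "best model")
})

test_that("empty task cells are emitted with NaN metrics, not dropped", {
  tab <- cached_table("grid", 2, 91,
                      c("steady_remission", "steady_depressed",
                        "swing_drastic", "swing_moderate"))
  # a cohort this small has some remission-only cells when filtered hard
  tab2 <- tab
  keep <- tab$samples$label != "steady_remission"
  tab2$samples <- tab$samples[keep, ]
  tab2$features <- tab$features[keep, ]
  rep <- run_grid(tab2, list(combos = "sleep", tasks = "remission_vs_drastic",
                             models = "logistic", k = 3))
  expect_equal(nrow(rep$cells), 1)
  expect_equal(rep$cells$n_steady, 0)
  expect_true(is.nan(rep$cells$acc_mean))
})
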