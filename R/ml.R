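# Classifier battery.
#
# The six classic classifiers benchmarked by the pipeline behind one
# interface: fit_classifier(method, X, y) and predict().  CART, random
# forest, Gaussian naive Bayes and the linear SVM are implemented here;
# KNN is backed by FNN and logistic regression by stats::glm.fit.
# All methods expect a numeric matrix X (imputed and standardized by the
# CV pipeline) and a two-level factor y.

ML_MODELS <- c("svm", "knn", "decision_tree", "naive_bayes",
               "random_forest", "logistic")

#' Fit one of the benchmark classifiers
#'
#' @param method one of `r paste(ML_MODELS, collapse = ", ")`.
#' @param X numeric matrix (samples x features), no missing values.
#' @param y factor with exactly two levels; the second level is treated as
#'   the positive class throughout the bench module.
#' @param params optional list of hyperparameters: `k` (KNN neighbors,
#'   default 5), `ntree`/`mtry` (random forest, default 100 /
#'   `floor(sqrt(p))`), `max_depth`/`min_split`/`min_leaf` (trees, default
#'   6/8/4), `lambda` (SVM L2 penalty, default 0.1), `var_floor`
#'   (naive Bayes, default 1e-9).
#' @return object of class `moodstab_model` with a [predict()] method.
#' @export
fit_classifier <- function(method, X, y, params = list()) {
  method <- match.arg(method, ML_MODELS)
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2) stop("y must have exactly two classes")
  X <- as.matrix(X)
  fit <- switch(method,
    logistic = fit_logistic(X, y),
    knn = list(X = X, y = y, k = params$k %||% 5),
    naive_bayes = fit_gnb(X, y, params$var_floor %||% 1e-9),
    decision_tree = build_tree(X, as.integer(y) - 1L,
                               max_depth = params$max_depth %||% 6,
                               min_split = params$min_split %||% 8,
                               min_leaf = params$min_leaf %||% 4),
    random_forest = fit_forest(X, y, ntree = params$ntree %||% 100,
                               mtry = params$mtry,
                               max_depth = params$max_depth %||% 6,
                               min_split = params$min_split %||% 8,
                               min_leaf = params$min_leaf %||% 4),
    svm = fit_linear_svm(X, y, lambda = params$lambda %||% 0.1))
  structure(list(method = method, fit = fit, levels = levels(y)),
            class = "moodstab_model")
}

#' @export
predict.moodstab_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  lv <- object$levels
  f <- object$fit
  pred <- switch(object$method,
    logistic = lv[(plogis(cbind(1, X) %*% f$beta) > 0.5) + 1],
    knn = as.character(FNN::knn(f$X, X, f$y, k = min(f$k, nrow(f$X)))),
    naive_bayes = predict_gnb(f, X, lv),
    decision_tree = lv[(predict_tree(f, X) > 0.5) + 1],
    random_forest = predict_forest(f, X, lv),
    svm = lv[(X %*% f$w + f$b > 0) + 1])
  factor(pred, levels = lv)
}

# ---- logistic regression ----

fit_logistic <- function(X, y) {
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, X), as.integer(y) - 1L,
                   family = stats::binomial()))
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  list(beta = beta)
}

# ---- Gaussian naive Bayes ----

fit_gnb <- function(X, y, var_floor) {
  cls <- levels(y)
  stats <- lapply(cls, function(cl) {
    Xi <- X[y == cl, , drop = FALSE]
    list(mu = colMeans(Xi),
         var = pmax(apply(Xi, 2, stats::var), var_floor),
         logprior = log(nrow(Xi) / nrow(X)))
  })
  names(stats) <- cls
  stats
}

predict_gnb <- function(f, X, lv) {
  ll <- vapply(lv, function(cl) {
    s <- f[[cl]]
    v <- s$var; v[!is.finite(v) | v <= 0] <- 1e-9
    rowSums(sweep(-0.5 * sweep(X, 2, s$mu)^2, 2, v, "/") -
              0.5 * rep(log(2 * pi * v), each = nrow(X))) + s$logprior
  }, numeric(nrow(X)))
  lv[max.col(ll, ties.method = "first")]
}

# ---- CART (greedy Gini) ----

gini_node <- function(pos, n) {
  if (n == 0) return(0)
  p <- pos / n
  1 - p^2 - (1 - p)^2
}

# best threshold for one feature; returns impurity sum of children (weighted
# by counts), threshold, or NULL when no valid split exists
best_split_feature <- function(x, y01, min_leaf) {
  o <- order(x)
  xs <- x[o]; ys <- y01[o]
  n <- length(xs)
  cpos <- cumsum(ys)
  k <- seq_len(n - 1)
  valid <- xs[k] < xs[k + 1] & k >= min_leaf & (n - k) >= min_leaf
  if (!any(valid)) return(NULL)
  k <- k[valid]
  nl <- k; nr <- n - k
  pl <- cpos[k] / nl; pr <- (cpos[n] - cpos[k]) / nr
  imp <- nl * (1 - pl^2 - (1 - pl)^2) + nr * (1 - pr^2 - (1 - pr)^2)
  i <- which.min(imp)
  list(impurity = imp[i], threshold = (xs[k[i]] + xs[k[i] + 1]) / 2)
}

build_tree <- function(X, y01, max_depth = 6, min_split = 8, min_leaf = 4,
                       mtry = NULL, importance = NULL) {
  if (is.null(importance)) importance <- numeric(ncol(X))
  grow <- function(idx, depth) {
    n <- length(idx)
    pos <- sum(y01[idx])
    node <- list(leaf = TRUE, pred = pos / n, n = n)
    if (depth >= max_depth || n < min_split || pos == 0 || pos == n)
      return(node)
    feats <- if (is.null(mtry)) seq_len(ncol(X)) else
      sample.int(ncol(X), min(mtry, ncol(X)))
    best <- NULL
    for (j in feats) {
      sp <- best_split_feature(X[idx, j], y01[idx], min_leaf)
      if (!is.null(sp) && (is.null(best) || sp$impurity < best$impurity)) {
        best <- sp; best$feature <- j
      }
    }
    if (is.null(best)) return(node)
    parent_imp <- n * gini_node(pos, n)
    if (parent_imp - best$impurity <= 1e-12) return(node)
    importance[best$feature] <<- importance[best$feature] +
      (parent_imp - best$impurity)
    left <- idx[X[idx, best$feature] <= best$threshold]
    right <- idx[X[idx, best$feature] > best$threshold]
    list(leaf = FALSE, feature = best$feature, threshold = best$threshold,
         n = n, left = grow(left, depth + 1), right = grow(right, depth + 1))
  }
  root <- grow(seq_len(nrow(X)), 0)
  list(root = root, importance = importance, p = ncol(X))
}

predict_tree <- function(tree, X) {
  out <- numeric(nrow(X))
  walk <- function(node, idx) {
    if (length(idx) == 0) return()
    if (node$leaf) { out[idx] <<- node$pred; return() }
    go_left <- X[idx, node$feature] <= node$threshold
    walk(node$left, idx[go_left])
    walk(node$right, idx[!go_left])
  }
  walk(tree$root, seq_len(nrow(X)))
  out
}

# ---- random forest (bagged CART with feature subsampling) ----

fit_forest <- function(X, y, ntree = 100, mtry = NULL, ...) {
  n <- nrow(X); p <- ncol(X)
  if (is.null(mtry)) mtry <- max(1, floor(sqrt(p)))
  y01 <- as.integer(y) - 1L
  importance <- numeric(p)
  trees <- vector("list", ntree)
  for (b in seq_len(ntree)) {
    idx <- sample.int(n, n, replace = TRUE)
    tr <- build_tree(X[idx, , drop = FALSE], y01[idx], mtry = mtry, ...)
    importance <- importance + tr$importance
    trees[[b]] <- tr
  }
  imp <- importance / ntree
  names(imp) <- colnames(X)
  list(trees = trees, importance = imp)
}

predict_forest <- function(f, X, lv) {
  votes <- rowMeans(vapply(f$trees,
                           function(tr) as.numeric(predict_tree(tr, X) > 0.5),
                           numeric(nrow(X))))
  lv[(votes > 0.5) + 1]
}

# ---- linear SVM (L2-regularized squared hinge, BFGS) ----

fit_linear_svm <- function(X, y, lambda = 0.1) {
  n <- nrow(X); p <- ncol(X)
  ys <- ifelse(as.integer(y) == 2, 1, -1)
  obj <- function(theta) {
    w <- theta[seq_len(p)]; b <- theta[p + 1]
    m <- pmax(0, 1 - ys * (X %*% w + b))
    lambda / 2 * sum(w^2) + mean(m^2)
  }
  grad <- function(theta) {
    w <- theta[seq_len(p)]; b <- theta[p + 1]
    m <- pmax(0, 1 - ys * (drop(X %*% w) + b))
    gw <- lambda * w - 2 / n * drop(crossprod(X, m * ys))
    gb <- -2 / n * sum(m * ys)
    c(gw, gb)
  }
  res <- stats::optim(numeric(p + 1), obj, grad, method = "BFGS",
                      control = list(maxit = 200))
  list(w = res$par[seq_len(p)], b = res$par[p + 1])
}
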