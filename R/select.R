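# Feature selection: the two schemes described for the study —
# L1-penalized linear models (sparse coefficients) and tree-ensemble
# importance ranking.  Both are designed to run inside each CV training
# fold; the interface takes plain matrices so the bench module can feed it
# fold-local standardized data.

#' L1-based feature selection
#'
#' Fits an L1-penalized logistic regression (lasso) at penalty `strength`
#' and selects the features with nonzero coefficients.  Constant columns
#' can never be selected.
#'
#' @param X numeric matrix, imputed and standardized.
#' @param y two-level factor.
#' @param strength the L1 penalty \eqn{\lambda} (default 0.05); larger
#'   values select fewer features.
#' @param seed RNG seed (glmnet's coordinate descent is deterministic, but
#'   the seed is recorded for provenance).
#' @return object of class `selection_result`: `method`, `selected`
#'   (names), `scores` (|coefficient| for selected features),
#'   `hyperparameters`, `seed`.
#' @export
select_l1 <- function(X, y, strength = 0.05, seed = 1L) {
  X <- as.matrix(X)
  nm <- colnames(X) %||% paste0("V", seq_len(ncol(X)))
  colnames(X) <- nm
  if (min(table(y)) < 2)  # lasso logistic needs >= 2 per class; select nothing
    return(structure(list(method = "l1", selected = character(0),
                          scores = numeric(0),
                          hyperparameters = list(strength = strength),
                          seed = seed), class = "selection_result"))
  Xg <- if (ncol(X) == 1) cbind(X, .pad = 0) else X  # glmnet needs >= 2 cols
  fit <- glmnet::glmnet(Xg, y, family = "binomial", alpha = 1,
                        lambda = strength, standardize = FALSE)
  beta <- as.numeric(fit$beta)
  names(beta) <- colnames(Xg)
  beta <- beta[nm]
  sel <- nm[beta != 0]
  scores <- abs(beta[beta != 0])
  structure(list(method = "l1",
                 selected = sel[order(-scores)],
                 scores = scores[order(-scores)],
                 hyperparameters = list(strength = strength),
                 seed = seed),
            class = "selection_result")
}

#' Tree-based feature selection
#'
#' Fits a random forest and ranks features by mean Gini impurity decrease;
#' features with importance at or above `threshold` are selected.  The
#' default threshold is the mean importance, so roughly the
#' above-average-contribution features survive; `threshold = 0` selects
#' everything.
#'
#' @param X numeric matrix, imputed and standardized.
#' @param y two-level factor.
#' @param threshold importance cutoff; NULL (default) uses the mean
#'   importance.
#' @param seed RNG seed for the forest's bootstraps.
#' @param ntree forest size (default 100).
#' @return a `selection_result` (see [select_l1()]); `scores` are
#'   importances, rank-ordered.
#' @export
select_tree <- function(X, y, threshold = NULL, seed = 1L, ntree = 100) {
  X <- as.matrix(X)
  nm <- colnames(X) %||% paste0("V", seq_len(ncol(X)))
  colnames(X) <- nm
  set.seed(seed)
  f <- fit_forest(X, droplevels(as.factor(y)), ntree = ntree)
  imp <- f$importance
  thr <- threshold %||% mean(imp)
  sel <- nm[imp >= thr]
  o <- order(-imp[sel])
  structure(list(method = "tree",
                 selected = sel[o],
                 scores = imp[sel][o],
                 hyperparameters = list(threshold = thr, ntree = ntree),
                 seed = seed),
            class = "selection_result")
}

# dispatcher used by the CV pipeline; method "none" keeps all features
run_selection <- function(method, X, y, params = list(), seed = 1L) {
  switch(method,
    none = structure(list(method = "none",
                          selected = colnames(X) %||%
                            paste0("V", seq_len(ncol(X))),
                          scores = NULL, hyperparameters = list(),
                          seed = seed),
                     class = "selection_result"),
    l1 = select_l1(X, y, params$l1_strength %||% 0.05, seed),
    tree = select_tree(X, y, params$tree_threshold,
                       seed, params$ntree %||% 100),
    stop("unknown selection method: ", method))
}
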