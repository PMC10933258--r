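#' Recursive feature elimination with cross-validation
#'
#' A linear-margin one-vs-rest support vector machine is fitted repeatedly;
#' at each step the feature with the smallest aggregate coefficient weight
#' (sum of squared coefficients across the one-vs-rest decision functions)
#' is eliminated, one feature per step, yielding a full elimination ranking.
#' Candidate subset sizes along the ranking are then scored by stratified-CV
#' macro balanced accuracy and the size with the maximum mean score is
#' selected, ties broken toward the smaller subset.
#'
#' @param X scaled feature matrix (no missing values)
#' @param y labels (>= 2 classes)
#' @param cv_folds stratified CV fold count
#' @param seed integer seed
#' @param cost SVM regularization parameter used by the estimator
#' @param size_grid subset sizes to score; `NULL` scores every size up to
#'   `ncol(X)` when there are at most `score_all_below` features, and a
#'   near-geometric grid of about 40 sizes otherwise
#' @param score_all_below threshold below which every size is scored
#' @return List with `subset` (selected feature names), `trace` (data.frame
#'   size/score), and `ranking` (elimination order, best first).
#' @export
rfe_cv_select <- function(X, y, cv_folds = 5L, seed = 1L, cost = 1,
                          size_grid = NULL, score_all_below = 60L) {
  X <- as.matrix(X)
  y <- factor(as.character(y))
  if (nlevels(y) < 2L) stop("need >= 2 classes", call. = FALSE)
  if (anyNA(X)) stop("impute before selection", call. = FALSE)
  if (min(table(y)) < cv_folds) {
    stop("fewer subjects than folds in at least one class", call. = FALSE)
  }
  d <- ncol(X)
  ranking <- rfe_ranking(X, y, cost)
  sizes <- if (!is.null(size_grid)) {
    sort(unique(pmin(pmax(as.integer(size_grid), 1L), d)))
  } else if (d <= score_all_below) {
    seq_len(d)
  } else {
    sort(unique(c(1L, round(exp(seq(log(2), log(d), length.out = 40L))), d)))
  }
  folds_id <- make_stratified_folds(y, cv_folds, seed = seed)
  trace <- data.frame(size = sizes, score = NA_real_)
  for (i in seq_along(sizes)) {
    feats <- ranking[seq_len(sizes[i])]
    preds <- rep(NA_character_, length(y))
    for (f in sort(unique(folds_id))) {
      tr <- folds_id != f
      fit <- svm_linear_multiclass(X[tr, feats, drop = FALSE], y[tr], cost)
      preds[!tr] <- as.character(stats::predict(fit, X[!tr, feats, drop = FALSE]))
    }
    trace$score[i] <- macro_balanced_accuracy(y, preds)
  }
  best_size <- trace$size[trace$score == max(trace$score)][1L]  # smallest on ties
  list(subset = ranking[seq_len(best_size)], trace = trace, ranking = ranking)
}

svm_linear_multiclass <- function(X, y, cost) {
  e1071::svm(x = X, y = y, kernel = "linear", cost = cost,
             scale = FALSE, tolerance = 1e-4)
}

# one-vs-rest linear SVM squared-coefficient aggregation per feature
ovr_svm_weights <- function(X, y, cost) {
  w2 <- numeric(ncol(X))
  for (cl in levels(y)) {
    yy <- factor(y == cl, levels = c(FALSE, TRUE))
    if (length(unique(yy)) < 2L) next
    fit <- e1071::svm(x = X, y = yy, kernel = "linear", cost = cost,
                      scale = FALSE, tolerance = 1e-4)
    w <- crossprod(fit$coefs, fit$SV)  # 1 x d decision-function coefficients
    w2 <- w2 + as.numeric(w)^2
  }
  w2
}

# full elimination ranking (best-first); the last-eliminated feature ranks
# first
rfe_ranking <- function(X, y, cost = 1) {
  alive <- colnames(X)
  order_out <- character(0)
  while (length(alive) > 1L) {
    w2 <- ovr_svm_weights(X[, alive, drop = FALSE], y, cost)
    drop_i <- which.min(w2)  # earliest index on ties: deterministic
    order_out <- c(alive[drop_i], order_out)
    alive <- alive[-drop_i]
  }
  c(alive, order_out)
}

#' Random-forest importance selection
#'
#' Fits an ensemble of randomized decision trees on all features and keeps
#' those whose normalized impurity-decrease importance is at or above a
#' threshold. The published procedure names no threshold value; the default
#' is the mean importance, which adapts to the feature count.
#'
#' @param X scaled feature matrix
#' @param y labels
#' @param n_trees forest size
#' @param seed integer seed
#' @param threshold_rule `"mean"` or a numeric threshold on the normalized
#'   importances
#' @return List with `subset` (kept feature names) and `importances`
#'   (named, normalized to sum 1).
#' @export
importance_select <- function(X, y, n_trees = 500L, seed = 1L,
                              threshold_rule = "mean") {
  X <- as.matrix(X)
  y <- factor(as.character(y))
  if (nlevels(y) < 2L) stop("need >= 2 classes", call. = FALSE)
  if (anyNA(X)) stop("impute before selection", call. = FALSE)
  fit <- ranger::ranger(
    x = as.data.frame(X, check.names = FALSE), y = y,
    num.trees = n_trees, importance = "impurity",
    seed = as.integer(seed), num.threads = 1L
  )
  imp <- fit$variable.importance
  imp <- pmax(imp, 0)
  imp <- imp / sum(imp)
  names(imp) <- colnames(X)
  thr <- if (identical(threshold_rule, "mean")) mean(imp) else as.numeric(threshold_rule)
  list(subset = names(imp)[imp >= thr], importances = imp, threshold = thr)
}

#' Intersect two selected feature subsets
#'
#' The optimum subset is the intersection of the RFE-CV and
#' importance-threshold selections. An empty intersection raises a warning
#' and, when `union_fallback` is set, falls back to the union so the
#' pipeline can proceed.
#'
#' @param a,b feature-name sets
#' @param union_fallback use the union when the intersection is empty
#' @return Character vector in canonical feature order.
#' @export
intersect_subsets <- function(a, b, union_fallback = TRUE) {
  canon <- enumerate_feature_names()
  bad <- setdiff(c(a, b), canon)
  if (length(bad) > 0L) {
    stop("non-canonical feature name(s): ",
         paste(utils::head(bad, 3), collapse = ", "), call. = FALSE)
  }
  out <- intersect(a, b)
  if (length(out) == 0L) {
    warning("feature-subset intersection is empty",
            if (union_fallback) "; falling back to the union" else "",
            call. = FALSE)
    if (union_fallback) out <- union(a, b)
  }
  canon[canon %in% out]
}

#' Full feature-selection stage
#'
#' Runs [rfe_cv_select()] and [importance_select()] on the same data and
#' intersects the two subsets.
#'
#' @inheritParams rfe_cv_select
#' @param n_trees forest size for the importance selection
#' @param threshold_rule importance threshold rule
#' @param union_fallback see [intersect_subsets()]
#' @return Object of class `selection_result` with `rfe_subset`,
#'   `rfe_score_trace`, `importance_subset`, `importances`, `final_subset`,
#'   and `provenance`.
#' @export
select_features <- function(X, y, cv_folds = 5L, seed = 1L, cost = 1,
                            size_grid = NULL, n_trees = 500L,
                            threshold_rule = "mean", union_fallback = TRUE) {
  rfe <- rfe_cv_select(X, y, cv_folds = cv_folds, seed = child_seed(seed, 1L),
                       cost = cost, size_grid = size_grid)
  imp <- importance_select(X, y, n_trees = n_trees,
                           seed = child_seed(seed, 2L),
                           threshold_rule = threshold_rule)
  final <- intersect_subsets(rfe$subset, imp$subset, union_fallback = union_fallback)
  structure(
    list(rfe_subset = rfe$subset, rfe_score_trace = rfe$trace,
         rfe_ranking = rfe$ranking,
         importance_subset = imp$subset, importances = imp$importances,
         final_subset = final,
         provenance = list(seed = seed, cv_folds = cv_folds, cost = cost,
                           n_trees = n_trees, threshold_rule = threshold_rule)),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat("Feature selection\n")
  cat(sprintf("  RFE-CV subset:        %d features (best CV score %.3f)\n",
              length(x$rfe_subset), max(x$rfe_score_trace$score)))
  cat(sprintf("  importance subset:    %d features\n", length(x$importance_subset)))
  cat(sprintf("  intersection (final): %d features\n", length(x$final_subset)))
  invisible(x)
}
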