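#' Stratified train/test split
#'
#' Samples, per class and without replacement, `round-half-up(ratio * class
#' size)` test subjects (at least 1), so the per-class test share stays
#' within one subject of the global ratio. Deterministic by seed.
#'
#' @param table feature table with `subject_id` and `condition` columns
#' @param ratio held-out test fraction (default 0.15; training keeps 0.85)
#' @param seed integer seed
#' @return Object of class `split_result` with `train_ids`, `test_ids`,
#'   `ratio`, `seed`.
#' @export
stratified_split <- function(table, ratio = 0.15, seed = 1L) {
  if (ratio <= 0 || ratio >= 1) stop("ratio must lie strictly inside (0, 1)", call. = FALSE)
  y <- table$condition
  ids <- table$subject_id
  sizes <- table(y)
  if (any(sizes < 2L)) {
    stop("every class needs >= 2 subjects to split; too small: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "), call. = FALSE)
  }
  test_ids <- character(0)
  with_seed(seed, {
    for (cl in sort(names(sizes))) {
      cl_ids <- ids[y == cl]
      n_test <- max(1L, round_half_up(ratio * length(cl_ids)))
      test_ids <- c(test_ids, sample(cl_ids, n_test))
    }
  })
  structure(list(train_ids = setdiff(ids, test_ids), test_ids = test_ids,
                 ratio = ratio, seed = as.integer(seed)),
            class = "split_result")
}

#' Default hyperparameters for the four base classifiers
#'
#' Moderate settings used when no tuning is run. `paper_preset()` returns
#' the published tuned configuration instead: linear-kernel SVM with C = 70;
#' a 6984-tree random forest (GINI, minimum split 2, minimum leaf 1, depth
#' 40, sqrt-of-features candidates, bootstrapped); ridge-penalized logistic
#' regression with C = 0.7, SAG solver, 5000 iterations; and KNN with the
#' Manhattan metric, 6 neighbors, uniform weights, leaf size 10.
#'
#' @return Named list with elements `svm`, `rf`, `lregr`, `knn`.
#' @export
default_hyperparameters <- function() {
  list(
    svm = list(kernel = "linear", cost = 10, gamma = 0.01),
    rf = list(num_trees = 300L, criterion = "gini", min_split = 2L,
              min_leaf = 1L, max_depth = 0L, max_features = "sqrt",
              bootstrap = TRUE),
    lregr = list(C = 1, solver = "sag", max_iter = 5000L),
    knn = list(metric = "manhattan", k = 6L, weights = "uniform", leaf_size = 10L)
  )
}

#' @rdname default_hyperparameters
#' @param algorithm one of `"svm"`, `"rf"`, `"lregr"`, `"knn"`, or `"all"`
#' @export
paper_preset <- function(algorithm = c("all", "svm", "rf", "lregr", "knn")) {
  algorithm <- match.arg(algorithm)
  preset <- list(
    svm = list(kernel = "linear", cost = 70, gamma = 0.01),
    rf = list(num_trees = 6984L, criterion = "gini", min_split = 2L,
              min_leaf = 1L, max_depth = 40L, max_features = "sqrt",
              bootstrap = TRUE),
    lregr = list(C = 0.7, solver = "sag", max_iter = 5000L),
    knn = list(metric = "manhattan", k = 6L, weights = "uniform", leaf_size = 10L)
  )
  if (algorithm == "all") preset else preset[[algorithm]]
}

#' Randomized/grid search spaces for hyperparameter tuning
#'
#' SVM: kernel, kernel coefficient (gamma), regularization parameter.
#' RF: tree count, split criterion, minimum node sizes, maximum depth,
#' feature-candidate rule, bootstrapping. LREGR: regularization strength and
#' iteration cap (searched by exhaustive grid, as its convergence is the
#' fragile part). KNN: distance metric, weight function, neighbor count,
#' leaf size.
#'
#' @return Named list of per-algorithm parameter ranges.
#' @export
default_search_space <- function() {
  list(
    svm = list(kernel = c("linear", "radial"),
               cost = 10^seq(-1, 2, by = 0.5),
               gamma = 10^seq(-3, 0, by = 1)),
    rf = list(num_trees = c(100L, 300L, 500L, 1000L),
              criterion = c("gini", "extratrees"),
              min_split = c(2L, 5L), min_leaf = c(1L, 2L, 5L),
              max_depth = c(0L, 10L, 20L, 40L),
              max_features = c("sqrt", "log2"), bootstrap = c(TRUE, FALSE)),
    lregr = list(C = c(0.01, 0.1, 0.7, 1, 10, 100),
                 solver = "sag", max_iter = c(1000L, 5000L)),
    knn = list(metric = c("manhattan", "euclidean"),
               weights = c("uniform", "distance"),
               k = c(1L, 3L, 5L, 6L, 8L, 10L, 15L),
               leaf_size = c(10L, 30L))
  )
}

# ---- base model fitting --------------------------------------------------
# All four fitters share one internal contract: fit_model() returns a
# `gait_base_model` whose predict_prob() yields an n x n_classes probability
# matrix with columns in sorted class order.

fit_model <- function(algorithm, X, y, params, seed = 1L) {
  if (any(!is.finite(X))) stop("non-finite feature values", call. = FALSE)
  y <- factor(as.character(y), levels = sort(unique(as.character(y))))
  fit <- with_seed(seed, switch(algorithm,
    svm = e1071::svm(x = X, y = y, kernel = params$kernel, cost = params$cost,
                     gamma = params$gamma %||% (1 / ncol(X)),
                     probability = TRUE, tolerance = 1e-4, scale = FALSE),
    rf = {
      mtry <- switch(as.character(params$max_features),
        "sqrt" = max(1L, floor(sqrt(ncol(X)))),
        "log2" = max(1L, floor(log2(ncol(X)))),
        max(1L, floor(as.numeric(params$max_features) * ncol(X)))
      )
      ranger::ranger(
        x = as.data.frame(X, check.names = FALSE), y = y, probability = TRUE,
        num.trees = params$num_trees,
        splitrule = if (identical(params$criterion, "extratrees")) "extratrees" else "gini",
        min.node.size = params$min_leaf %||% 1L,
        max.depth = if ((params$max_depth %||% 0L) > 0L) params$max_depth else NULL,
        mtry = mtry, replace = isTRUE(params$bootstrap),
        seed = as.integer(seed), num.threads = 1L
      )
    },
    lregr = {
      # one-vs-rest ridge-penalized logistic regression; lambda = 1/(C*n)
      lambda <- 1 / (params$C * nrow(X))
      Xg <- if (ncol(X) == 1L) cbind(X, `..pad` = 0) else X
      fits <- lapply(levels(y), function(cl) {
        glmnet::glmnet(Xg, factor(y == cl, levels = c(FALSE, TRUE)),
                       family = "binomial", alpha = 0, lambda = lambda,
                       maxit = params$max_iter %||% 5000L, thresh = 1e-8,
                       standardize = FALSE)
      })
      names(fits) <- levels(y)
      fits
    },
    knn = list(X = X, y = y, params = params),
    stop("unknown algorithm: ", algorithm, call. = FALSE)
  ))
  structure(list(algorithm = algorithm, params = params, fit = fit,
                 classes = levels(y), feature_names = colnames(X),
                 seed = as.integer(seed)),
            class = "gait_base_model")
}

predict_prob <- function(model, X) {
  stopifnot(inherits(model, "gait_base_model"))
  if (!is.null(model$feature_names)) {
    if (is.null(colnames(X)) || !all(model$feature_names %in% colnames(X))) {
      stop("feature-set mismatch between model and new data", call. = FALSE)
    }
    X <- X[, model$feature_names, drop = FALSE]
  }
  cls <- model$classes
  p <- switch(model$algorithm,
    svm = {
      pr <- attr(stats::predict(model$fit, X, probability = TRUE), "probabilities")
      pr[, cls, drop = FALSE]
    },
    rf = {
      pr <- stats::predict(model$fit,
                           data = as.data.frame(X, check.names = FALSE))$predictions
      pr[, cls, drop = FALSE]
    },
    lregr = {
      Xg <- if (ncol(X) == 1L) cbind(X, `..pad` = 0) else X
      raw <- vapply(cls, function(cl) {
        as.numeric(stats::predict(model$fit[[cl]], Xg, type = "response"))
      }, numeric(nrow(X)))
      raw <- matrix(raw, nrow = nrow(X), dimnames = list(NULL, cls))
      raw / rowSums(raw)
    },
    knn = knn_prob(model$fit, X)
  )
  rownames(p) <- NULL
  p
}

# exact brute-force k-nearest-neighbor class probabilities; the distance
# matrix is accumulated feature-wise to stay vectorized
knn_prob <- function(fit, X) {
  cls <- levels(fit$y)
  k <- min(fit$params$k, nrow(fit$X))
  metric <- fit$params$metric %||% "manhattan"
  D <- matrix(0, nrow(X), nrow(fit$X))
  for (f in seq_len(ncol(X))) {
    df <- outer(X[, f], fit$X[, f], "-")
    D <- D + if (metric == "manhattan") abs(df) else df^2
  }
  if (metric != "manhattan") D <- sqrt(D)
  out <- matrix(0, nrow(X), length(cls), dimnames = list(NULL, cls))
  y_int <- as.integer(fit$y)
  for (i in seq_len(nrow(X))) {
    nb <- order(D[i, ])[seq_len(k)]
    w <- if (identical(fit$params$weights, "distance")) {
      1 / pmax(D[i, nb], 1e-12)
    } else rep(1, k)
    for (j in seq_len(k)) out[i, y_int[nb[j]]] <- out[i, y_int[nb[j]]] + w[j]
  }
  out / rowSums(out)
}

# ---- stratified CV helpers ----------------------------------------------

make_stratified_folds <- function(y, k, seed = 1L) {
  y <- as.character(y)
  folds <- integer(length(y))
  with_seed(seed, {
    for (cl in sort(unique(y))) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

cv_score <- function(algorithm, X, y, params, folds_id, seed = 1L) {
  preds <- rep(NA_character_, length(y))
  for (f in sort(unique(folds_id))) {
    tr <- folds_id != f
    if (length(unique(y[tr])) < 2L) return(NA_real_)
    m <- fit_model(algorithm, X[tr, , drop = FALSE], y[tr], params,
                   seed = child_seed(seed, f))
    p <- predict_prob(m, X[!tr, , drop = FALSE])
    preds[!tr] <- colnames(p)[max.col(p, ties.method = "first")]
  }
  macro_balanced_accuracy(y, preds)
}

#' Tune one base classifier's hyperparameters
#'
#' Randomized search for the SVM, random forest, and KNN; exhaustive grid
#' search for the logistic regression. The objective is mean stratified-CV
#' macro balanced accuracy on the training data. `preset = "paper"`
#' bypasses the search and returns the published tuned configuration.
#'
#' @param algorithm `"svm"`, `"rf"`, `"lregr"`, or `"knn"`
#' @param X training feature matrix (scaled)
#' @param y training labels
#' @param space search space (see [default_search_space()])
#' @param budget number of randomized draws (ignored for the grid search)
#' @param seed integer seed
#' @param folds CV fold count
#' @param preset `"paper"` to load the published configuration
#' @return Named list of tuned hyperparameters with attributes `score`
#'   (CV balanced accuracy) and `trace`.
#' @export
tune_hyperparameters <- function(algorithm, X, y, space = default_search_space(),
                                 budget = 20L, seed = 1L, folds = 3L,
                                 preset = NULL) {
  if (identical(preset, "paper")) return(paper_preset(algorithm))
  if (budget < 1L) stop("search budget must be >= 1", call. = FALSE)
  sp <- space[[algorithm]]
  grid <- expand.grid(sp, stringsAsFactors = FALSE)
  configs <- if (algorithm == "lregr") {
    lapply(seq_len(nrow(grid)), function(i) as.list(grid[i, , drop = FALSE]))
  } else {
    with_seed(seed, {
      rows <- sample.int(nrow(grid), size = min(budget, nrow(grid)))
      lapply(rows, function(i) as.list(grid[i, , drop = FALSE]))
    })
  }
  folds_id <- make_stratified_folds(y, folds, seed = child_seed(seed, 17L))
  scores <- vapply(seq_along(configs), function(i) {
    cv_score(algorithm, X, y, configs[[i]], folds_id, seed = child_seed(seed, i))
  }, numeric(1))
  best <- which.max(scores)
  out <- configs[[best]]
  attr(out, "score") <- scores[best]
  attr(out, "trace") <- data.frame(config = seq_along(scores), score = scores)
  out
}

# ---- the ensemble --------------------------------------------------------

#' Fit the four-model soft-voting ensemble
#'
#' The core classifier: a support vector machine, a random forest, a
#' one-vs-rest ridge-penalized logistic regression, and a k-nearest-neighbor
#' model, each exposing class probabilities, combined by a weighted soft
#' vote `P = sum_m w_m P_m` with nonnegative weights summing to one.
#' Iterative learners run to a loss-change tolerance of 1e-4 rather than a
#' hard iteration cap (the logistic regression is capped at its tuned
#' maximum). Voting weights default to equal and can be optimized on a
#' validation set with [optimize_vote_weights()].
#'
#' @param x feature matrix or data.frame of scaled training features, or a
#'   formula such as `condition ~ .`
#' @param y training labels (omit when `x` is a formula)
#' @param data data.frame holding the variables when `x` is a formula
#' @param hyperparameters list with elements `svm`, `rf`, `lregr`, `knn`
#'   (see [default_hyperparameters()], [paper_preset()],
#'   [tune_hyperparameters()])
#' @param weights voting weights (length 4, nonnegative; normalized to sum 1)
#' @param seed integer seed for all stochastic fitting internals
#' @param ... passed between methods
#' @return Object of class `gait_ensemble` with fitted base models, voting
#'   weights, class order, and feature names.
#' @export
gait_ensemble <- function(x, ...) UseMethod("gait_ensemble")

#' @rdname gait_ensemble
#' @export
gait_ensemble.formula <- function(x, data, ...) {
  mf <- stats::model.frame(x, data = data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  feats <- setdiff(names(mf), names(mf)[1L])
  X <- as.matrix(data[, feats, drop = FALSE])
  obj <- gait_ensemble.default(X, y, ...)
  obj$call <- match.call()
  obj
}

#' @rdname gait_ensemble
#' @export
gait_ensemble.default <- function(x, y, hyperparameters = default_hyperparameters(),
                                  weights = NULL, seed = 1L, ...) {
  X <- as.matrix(x)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  algos <- c("svm", "rf", "lregr", "knn")
  models <- lapply(seq_along(algos), function(i) {
    fit_model(algos[i], X, y, hyperparameters[[algos[i]]],
              seed = child_seed(seed, i))
  })
  names(models) <- algos
  w <- weights %||% rep(1, 4)
  if (length(w) != 4L || any(w < 0) || sum(w) <= 0) {
    stop("voting weights must be 4 nonnegative numbers with positive sum",
         call. = FALSE)
  }
  structure(
    list(models = models, weights = stats::setNames(w / sum(w), algos),
         classes = sort(unique(as.character(y))),
         feature_names = colnames(X), seed = as.integer(seed),
         call = match.call()),
    class = "gait_ensemble"
  )
}

#' @rdname gait_ensemble
#' @export
train_bundle <- function(x, y, hyperparameters = default_hyperparameters(),
                         seed = 1L) {
  gait_ensemble.default(x, y, hyperparameters = hyperparameters, seed = seed)
}

#' Optimize the soft-voting weights
#'
#' Samples `budget` weight vectors uniformly on the 4-simplex and returns
#' the one maximizing validation macro balanced accuracy of the weighted
#' probability vote. Ties go to the earlier draw; deterministic by seed.
#'
#' @param bundle a fitted [gait_ensemble()]
#' @param X_val validation feature matrix
#' @param y_val validation labels
#' @param budget number of sampled weight vectors
#' @param seed integer seed
#' @return The bundle with its `weights` replaced by the best vector
#'   (attribute `score` holds the attained balanced accuracy).
#' @export
optimize_vote_weights <- function(bundle, X_val, y_val, budget = 200L, seed = 1L) {
  stopifnot(inherits(bundle, "gait_ensemble"))
  if (budget < 1L) stop("budget must be >= 1", call. = FALSE)
  Xv <- prepare_matrix(bundle, X_val)
  probs <- lapply(bundle$models, function(m) predict_prob(m, Xv))
  draws <- with_seed(seed, {
    lapply(seq_len(budget), function(i) {
      g <- stats::rexp(4)
      g / sum(g)
    })
  })
  scores <- vapply(draws, function(w) {
    p <- Reduce(`+`, Map(`*`, probs, w))
    pred <- colnames(p)[max.col(p, ties.method = "first")]
    macro_balanced_accuracy(y_val, pred)
  }, numeric(1))
  best <- which.max(scores)
  bundle$weights <- stats::setNames(draws[[best]], names(bundle$models))
  attr(bundle$weights, "score") <- scores[best]
  bundle
}

prepare_matrix <- function(bundle, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) {
    if (ncol(X) != length(bundle$feature_names)) {
      stop("feature-set mismatch with the fitted ensemble", call. = FALSE)
    }
    colnames(X) <- bundle$feature_names
  }
  absent <- setdiff(bundle$feature_names, colnames(X))
  if (length(absent) > 0L) {
    stop("feature-set mismatch: new data lacks ",
         paste(utils::head(absent, 3), collapse = ", "), call. = FALSE)
  }
  X[, bundle$feature_names, drop = FALSE]
}

#' Soft-voting prediction
#'
#' Weighted average of the member models' class probabilities; the label is
#' the argmax, with probability ties broken toward the lexicographically
#' first class label.
#'
#' @param bundle a fitted [gait_ensemble()]
#' @param X feature matrix
#' @return List with `labels` (character) and `prob` (matrix, columns in
#'   sorted class order).
#' @export
predict_soft_vote <- function(bundle, X) {
  stopifnot(inherits(bundle, "gait_ensemble"))
  Xm <- prepare_matrix(bundle, X)
  probs <- lapply(bundle$models, function(m) predict_prob(m, Xm))
  p <- Reduce(`+`, Map(`*`, probs, as.numeric(bundle$weights)))
  labels <- colnames(p)[max.col(p, ties.method = "first")]
  list(labels = labels, prob = p)
}

#' @rdname gait_ensemble
#' @param object,newdata,type standard predict-method arguments; `type`
#'   `"class"` returns labels, `"prob"` the voted probability matrix,
#'   `"member_prob"` the per-model probability matrices
#' @export
predict.gait_ensemble <- function(object, newdata, type = c("class", "prob", "member_prob"),
                                  ...) {
  type <- match.arg(type)
  if (type == "member_prob") {
    Xm <- prepare_matrix(object, newdata)
    return(lapply(object$models, function(m) predict_prob(m, Xm)))
  }
  out <- predict_soft_vote(object, newdata)
  if (type == "class") out$labels else out$prob
}

#' @export
print.gait_ensemble <- function(x, ...) {
  cat("Weighted soft-voting gait classifier\n")
  cat(sprintf("  classes:  %d (%s, ...)\n", length(x$classes), x$classes[1L]))
  cat(sprintf("  features: %d\n", length(x$feature_names)))
  w <- round(as.numeric(x$weights), 3)
  cat(sprintf("  weights:  svm=%.3f rf=%.3f lregr=%.3f knn=%.3f\n",
              w[1], w[2], w[3], w[4]))
  invisible(x)
}

#' @export
summary.gait_ensemble <- function(object, ...) {
  print(object)
  cat("member hyperparameters:\n")
  for (m in names(object$models)) {
    p <- object$models[[m]]$params
    cat(sprintf("  %-6s %s\n", m,
                paste(names(p), unlist(lapply(p, format)), sep = "=", collapse = " ")))
  }
  invisible(object)
}

#' Repeated cross-validated evaluation of the ensemble pipeline
#'
#' For each repeat (fresh seeds) runs the chosen scheme -- stratified k-fold
#' or leave-one-out -- training a fresh ensemble per fold and pooling the
#' out-of-fold soft-vote predictions into one metrics report per repeat.
#' Optionally also records score-versus-sample-size traces for learning
#' curves. Leave-one-out is guarded by a sample cap because its cost grows
#' linearly in n; above the cap the k-fold scheme is advised.
#'
#' @param X feature matrix (scaled, selected)
#' @param y labels
#' @param hyperparameters ensemble hyperparameters
#' @param repeats number of repeats (fresh seeds each)
#' @param scheme `"stratified_kfold"` or `"leave_one_out"`
#' @param folds fold count for the k-fold scheme
#' @param seed integer master seed
#' @param loocv_cap largest n for which leave-one-out is allowed
#' @param learning_curve also evaluate at subsample fractions
#' @param curve_fractions training-set fractions for the learning curve
#' @return Object of class `cv_evaluation`: list with `metrics` (one
#'   metrics_report per repeat), `macro` (data.frame of macro rows), and
#'   optionally `curve`.
#' @export
repeated_cv_evaluate <- function(X, y, hyperparameters = default_hyperparameters(),
                                 repeats = 3L,
                                 scheme = c("stratified_kfold", "leave_one_out"),
                                 folds = 5L, seed = 1L, loocv_cap = 80L,
                                 learning_curve = FALSE,
                                 curve_fractions = c(0.4, 0.6, 0.8, 1)) {
  scheme <- match.arg(scheme)
  X <- as.matrix(X)
  n <- nrow(X)
  if (scheme == "leave_one_out" && n > loocv_cap) {
    stop(sprintf(paste0("leave-one-out over %d subjects exceeds the cap of %d; ",
                        "use scheme = 'stratified_kfold'"), n, loocv_cap),
         call. = FALSE)
  }
  run_scheme <- function(idx, rep_seed) {
    Xs <- X[idx, , drop = FALSE]; ys <- as.character(y)[idx]
    folds_id <- if (scheme == "leave_one_out") seq_along(idx)
                else make_stratified_folds(ys, folds, seed = rep_seed)
    preds <- rep(NA_character_, length(idx))
    for (f in sort(unique(folds_id))) {
      tr <- folds_id != f
      b <- train_bundle(Xs[tr, , drop = FALSE], ys[tr], hyperparameters,
                        seed = child_seed(rep_seed, f))
      preds[!tr] <- predict_soft_vote(b, Xs[!tr, , drop = FALSE])$labels
    }
    list(report = metrics_report(ys, preds))
  }
  reports <- list(); curve <- NULL
  for (r in seq_len(repeats)) {
    rep_seed <- child_seed(seed, 100L + r)
    reports[[r]] <- run_scheme(seq_len(n), rep_seed)$report
    if (learning_curve) {
      for (fr in curve_fractions) {
        idx <- with_seed(child_seed(rep_seed, 7L), {
          unlist(lapply(sort(unique(as.character(y))), function(cl) {
            cl_idx <- which(as.character(y) == cl)
            sample(cl_idx, max(2L, round_half_up(fr * length(cl_idx))))
          }))
        })
        rp <- run_scheme(idx, child_seed(rep_seed, 11L))$report
        curve <- rbind(curve, data.frame(
          repeat_id = r, fraction = fr, n = length(idx),
          balanced_accuracy = rp$balanced_accuracy[rp$class == "macro"]
        ))
      }
    }
  }
  macro <- do.call(rbind, lapply(seq_along(reports), function(r) {
    m <- reports[[r]][reports[[r]]$class == "macro",
                      c("balanced_accuracy", "recall", "precision", "f1")]
    cbind(repeat_id = r, m)
  }))
  rownames(macro) <- NULL
  structure(list(metrics = reports, macro = macro, curve = curve,
                 scheme = scheme, folds = if (scheme == "leave_one_out") n else folds),
            class = "cv_evaluation")
}

#' @export
print.cv_evaluation <- function(x, ...) {
  cat(sprintf("Repeated CV evaluation (%s, %d repeats)\n",
              x$scheme, nrow(x$macro)))
  print(round(x$macro, 3), row.names = FALSE)
  invisible(x)
}
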