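lime_background <- function(n = 150L, d = 6L, seed = 5L) {
  feats <- enumerate_feature_names()[seq_len(d)]
  withr::with_seed(seed, {
    B <- matrix(rnorm(n * d, mean = 10, sd = 4), n, d,
                dimnames = list(NULL, feats))
    B
  })
}

test_that("a single-signal model is attributed to its driving feature", {
  B <- lime_background()
  x <- B[1, ]
  f_sig <- colnames(B)[3]
  pf <- function(M) stats::plogis(0.8 * (M[, f_sig] - 10))
  hits <- vapply(1:20, function(s) {
    e <- lime_explain(pf, B, x, n_samples = 400L, seed = s)
    w <- abs(e$weights)
    names(which.max(w)) == f_sig
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("a constant model yields vanishing weights and seeds reproduce exactly", {
  B <- lime_background()
  x <- B[2, ]
  e <- lime_explain(function(M) rep(0.4, nrow(M)), B, x,
                    n_samples = 400L, seed = 3L)
  expect_lt(max(abs(e$weights)), 1e-8)

  pf <- function(M) stats::plogis(0.3 * M[, 1] - 0.2 * M[, 2])
  e1 <- lime_explain(pf, B, x, n_samples = 300L, seed = 11L)
  e2 <- lime_explain(pf, B, x, n_samples = 300L, seed = 11L)
  expect_identical(e1$weights, e2$weights)
  e3 <- lime_explain(pf, B, x, n_samples = 300L, seed = 12L)
  expect_false(identical(e1$weights, e3$weights))
})

test_that("constant background features are excluded with a note", {
  B <- lime_background()
  B[, 5] <- 7
  e <- lime_explain(function(M) stats::plogis(M[, 1] - 10), B, B[1, ],
                    n_samples = 200L, seed = 1L)
  expect_identical(e$excluded_constant, colnames(B)[5])
  expect_equal(e$weights[[colnames(B)[5]]], 0)
})

test_that("explanations are unit-consistent under min-max rescaling", {
  # for a linear model, explaining in original units must match explaining
  # in scaled units with weights divided by (max - min), seed-matched
  B <- lime_background(d = 4L)
  feats <- colnames(B)
  x <- B[4, ]
  beta <- c(0.05, -0.03, 0.08, 0)
  pf_orig <- function(M) 0.5 + M %*% beta / 10
  sc <- fit_scaler(as.data.frame(B, check.names = FALSE), features = feats)
  rng <- sc$max - sc$min
  Bs <- as.matrix(apply_scaler(as.data.frame(B, check.names = FALSE), sc)[, feats])
  xs <- (x - sc$min) / rng
  pf_scaled <- function(M) 0.5 + (sweep(sweep(M, 2, rng, "*"), 2, sc$min, "+") %*% beta) / 10
  e_orig <- lime_explain(pf_orig, B, x, n_samples = 500L, seed = 7L,
                         n_features = 4L)
  e_scaled <- lime_explain(pf_scaled, Bs, xs, n_samples = 500L, seed = 7L,
                           n_features = 4L)
  expect_equal(e_orig$weights, e_scaled$weights / rng, tolerance = 1e-6)
})

test_that("aggregation ranks by mean absolute weight with top-k membership counts", {
  feats <- enumerate_feature_names()[1:6]
  mk_expl <- function(w) {
    structure(list(weights = stats::setNames(w, feats), intercept = 0,
                   selected = feats, excluded_constant = character(0),
                   n_samples = 10L, seed = 1L, kernel_width = 1),
              class = "lime_explanation")
  }
  # feature 2 dominates on average; feature 6 never appears
  expl <- list(
    s1 = list(mv = mk_expl(c(0.1, 0.9, 0.2, 0.05, 0.3, 0))),
    s2 = list(mv = mk_expl(c(0.2, 0.8, 0.1, 0.02, 0.4, 0))),
    s3 = list(mv = mk_expl(c(0.15, 0.7, 0.3, 0.01, 0.2, 0)))
  )
  conds <- stats::setNames(rep("Clubfoot", 3), names(expl))
  tab <- aggregate_top_features(expl, conds, k = 3L, n_subjects = 20L, seed = 1L)
  expect_equal(tab$feature[tab$rank == 1L], feats[2])
  expect_equal(tab$n_sampled[1], 3L)
  expect_lte(max(table(tab$condition, tab$model)), 3L)
  expect_equal(tab$subject_count[tab$rank == 1L], 3L)  # in everyone's top 3

  # identical explanations: table top-k equals any single subject's top-k
  same <- list(s1 = expl$s1, s2 = expl$s1, s3 = expl$s1)
  tab2 <- aggregate_top_features(same, conds, k = 3L, seed = 1L)
  w <- abs(expl$s1$mv$weights)
  expect_identical(tab2$feature, names(sort(w, decreasing = TRUE))[1:3])

  # permuting subject order leaves the aggregate unchanged
  tab3 <- aggregate_top_features(expl[c(3, 1, 2)], conds, k = 3L, seed = 1L)
  expect_equal(as.data.frame(tab3), as.data.frame(tab))
})

test_that("the relevance report unifies per-model top features", {
  feats <- enumerate_feature_names()[1:4]
  tab <- structure(data.frame(
    condition = rep("Cavovarus", 4),
    model = c("svm", "svm", "mv", "mv"),
    rank = c(1L, 2L, 1L, 2L),
    feature = c(feats[1], feats[2], feats[1], feats[3]),
    mean_abs_weight = c(0.9, 0.5, 0.8, 0.4),
    subject_count = c(5L, 3L, 4L, 2L),
    n_sampled = 5L
  ), class = c("relevance_table", "data.frame"))
  json <- withr::local_tempfile(fileext = ".json")
  txt <- withr::local_tempfile(fileext = ".txt")
  rep <- relevance_report(tab, json_path = json, txt_path = txt)
  # a feature found by two models appears once, with one count per model
  expect_equal(sum(rep$feature == feats[1]), 1L)
  expect_equal(rep$count_svm[rep$feature == feats[1]], 5L)
  expect_equal(rep$count_mv[rep$feature == feats[1]], 4L)
  expect_equal(rep$count_svm[rep$feature == feats[3]], 0L)
  expect_true(file.exists(json))
  expect_match(readLines(txt), "Cavovarus", all = FALSE)
})

test_that("explain_subject shares one perturbation sample across the five models", {
  ft <- tiny_features()
  feats <- enumerate_feature_names()[c(1, 3, 32, 64, 95)]
  train <- ft[-41, ]  # keep every class represented in training
  sc <- fit_scaler(train, features = feats)
  tr_scaled <- apply_scaler(train, sc)
  X <- as.matrix(tr_scaled[, feats])
  b <- train_bundle(X, train$condition, seed = 2L)
  x <- stats::setNames(as.numeric(ft[41, feats]), feats)
  ex <- explain_subject(b, sc, train[, feats], x,
                        target_class = ft$condition[41],
                        n_samples = 150L, seed = 5L)
  expect_named(ex, c("svm", "rf", "lregr", "knn", "mv"))
  for (e in ex) {
    expect_s3_class(e, "lime_explanation")
    expect_true(all(is.finite(e$weights)))
    expect_named(e$weights, feats)
  }
})
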