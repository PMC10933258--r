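# linearly separable 2-class toy set with margin 2
separable_xy <- function(n_per = 20L, seed = 2L) {
  feats <- enumerate_feature_names()[1:2]
  withr::with_seed(seed, {
    X <- rbind(
      cbind(rnorm(n_per, -2, 0.3), rnorm(n_per, 0, 0.3)),
      cbind(rnorm(n_per, 2, 0.3), rnorm(n_per, 0, 0.3))
    )
    colnames(X) <- feats
    list(X = X, y = rep(c("left", "right"), each = n_per))
  })
}

test_that("stratified split follows the per-class rounding rule", {
  tab <- data.frame(
    subject_id = paste0("s", 1:120),
    condition = rep(c("A", "B"), times = c(100, 20))
  )
  sp <- stratified_split(tab, ratio = 0.15, seed = 4L)
  test_cond <- tab$condition[match(sp$test_ids, tab$subject_id)]
  expect_equal(sum(test_cond == "A"), 15L)
  expect_equal(sum(test_cond == "B"), 3L)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0L)
  expect_setequal(c(sp$train_ids, sp$test_ids), tab$subject_id)
  sp2 <- stratified_split(tab, ratio = 0.15, seed = 4L)
  expect_identical(sp$test_ids, sp2$test_ids)
  expect_error(stratified_split(tab, ratio = 0), "strictly inside")
  tiny <- data.frame(subject_id = c("a", "b", "c"),
                     condition = c("A", "A", "B"))
  expect_error(stratified_split(tiny, 0.15, 1), ">= 2 subjects")
})

test_that("the published tuned preset is reproduced verbatim", {
  svm <- paper_preset("svm")
  expect_equal(svm$kernel, "linear")
  expect_equal(svm$cost, 70)
  knn <- paper_preset("knn")
  expect_equal(knn$metric, "manhattan")
  expect_equal(knn$k, 6L)
  expect_equal(knn$weights, "uniform")
  expect_equal(knn$leaf_size, 10L)
  rf <- paper_preset("rf")
  expect_equal(rf$num_trees, 6984L)
  expect_equal(rf$max_depth, 40L)
  lregr <- paper_preset("lregr")
  expect_equal(lregr$C, 0.7)
  expect_equal(lregr$max_iter, 5000L)
  expect_identical(tune_hyperparameters("svm", preset = "paper"), svm)
})

test_that("hyperparameter search respects its budget and determinism", {
  d <- separable_xy()
  one <- tune_hyperparameters("knn", d$X, d$y, budget = 1L, seed = 6L, folds = 2L)
  space <- default_search_space()$knn
  expect_true(one$k %in% space$k)
  expect_true(one$metric %in% space$metric)
  again <- tune_hyperparameters("knn", d$X, d$y, budget = 1L, seed = 6L, folds = 2L)
  expect_identical(one[names(one)], again[names(again)])
  expect_error(tune_hyperparameters("svm", d$X, d$y, budget = 0L), "budget")
})

test_that("all four base models separate an easy margin and emit proper probabilities", {
  d <- separable_xy()
  b <- train_bundle(d$X, d$y, seed = 8L)
  for (m in names(b$models)) {
    p <- gaitpath:::predict_prob(b$models[[m]], d$X)
    expect_equal(unname(rowSums(p)), rep(1, nrow(d$X)), tolerance = 1e-9)
    pred <- colnames(p)[max.col(p, ties.method = "first")]
    expect_equal(macro_balanced_accuracy(d$y, pred), 1.0)
  }
  # refit with the same seed reproduces held-out predictions exactly
  b2 <- train_bundle(d$X, d$y, seed = 8L)
  probe <- matrix(c(-1.5, 0.2, 1.5, -0.2), 2, 2, byrow = TRUE,
                  dimnames = list(NULL, colnames(d$X)))
  expect_identical(predict(b, probe, type = "prob"),
                   predict(b2, probe, type = "prob"))
})

test_that("soft voting is a weighted probability mean with stated tie-breaks", {
  d <- separable_xy()
  b <- train_bundle(d$X, d$y, seed = 3L)
  b$weights <- stats::setNames(c(1, 0, 0, 0), names(b$models))
  out <- predict_soft_vote(b, d$X)
  svm_p <- gaitpath:::predict_prob(b$models$svm, d$X)
  expect_equal(out$prob, svm_p, tolerance = 1e-12)
  expect_identical(out$labels, colnames(svm_p)[max.col(svm_p, "first")])

  # hand-check the weighted mean through the member probabilities
  b$weights <- stats::setNames(rep(0.25, 4), names(b$models))
  member <- predict(b, d$X, type = "member_prob")
  manual <- Reduce(`+`, member) / 4
  expect_equal(predict(b, d$X, type = "prob"), manual, tolerance = 1e-12)

  # permuting members together with their weights changes nothing
  perm <- c("knn", "svm", "rf", "lregr")
  b3 <- b
  b3$models <- b$models[perm]
  b3$weights <- b$weights[perm]
  expect_equal(predict_soft_vote(b3, d$X)$prob, predict_soft_vote(b, d$X)$prob)

  expect_error(predict_soft_vote(b, d$X[, 1, drop = FALSE]), "mismatch")
})

test_that("predictions are invariant to feature-column permutation", {
  d <- separable_xy()
  b <- train_bundle(d$X, d$y, seed = 5L)
  shuffled <- d$X[, rev(colnames(d$X))]
  expect_equal(predict(b, d$X, type = "prob"),
               predict(b, shuffled, type = "prob"))
})

test_that("vote-weight optimization finds the dominant model", {
  # one member fitted on true labels, three on flipped labels: the flipped
  # members confidently predict the wrong class, so the vote is right only
  # when the good member holds the plurality of the mass
  d <- separable_xy(n_per = 25L)
  y_bad <- ifelse(d$y == "left", "right", "left")
  hp <- default_hyperparameters()
  good <- gaitpath:::fit_model("knn", d$X, d$y, hp$knn, seed = 1L)
  bad <- lapply(c("svm", "rf", "lregr"), function(a) {
    gaitpath:::fit_model(a, d$X, y_bad, hp[[a]], seed = 1L)
  })
  bundle <- structure(
    list(models = stats::setNames(c(list(good), bad),
                                  c("knn", "svm", "rf", "lregr")),
         weights = stats::setNames(rep(0.25, 4), c("knn", "svm", "rf", "lregr")),
         classes = sort(unique(d$y)), feature_names = colnames(d$X),
         seed = 1L),
    class = "gait_ensemble"
  )
  tuned <- optimize_vote_weights(bundle, d$X, d$y, budget = 300L, seed = 9L)
  expect_equal(which.max(tuned$weights), c(knn = 1L))
  expect_equal(attr(tuned$weights, "score"), 1.0)
  expect_equal(sum(tuned$weights), 1, tolerance = 1e-12)
  expect_true(all(tuned$weights >= 0))

  # budget 1 returns exactly the single sampled vector
  one <- optimize_vote_weights(bundle, d$X, d$y, budget = 1L, seed = 2L)
  expected <- withr::with_seed(2L, {g <- rexp(4); g / sum(g)})
  expect_equal(unname(as.numeric(one$weights)), expected, tolerance = 1e-12)
})

test_that("repeated CV evaluation has the declared fold structure", {
  d <- separable_xy(n_per = 10L)
  ev <- repeated_cv_evaluate(d$X, d$y, repeats = 2L, scheme = "leave_one_out",
                             seed = 21L)
  expect_equal(ev$folds, nrow(d$X))
  expect_equal(nrow(ev$macro), 2L)
  expect_true(all(ev$macro$balanced_accuracy == 1))

  ev2 <- repeated_cv_evaluate(d$X, d$y, repeats = 2L, scheme = "leave_one_out",
                              seed = 21L)
  expect_identical(ev$macro, ev2$macro)

  big <- matrix(rnorm(400), 200, 2,
                dimnames = list(NULL, colnames(d$X)))
  expect_error(
    repeated_cv_evaluate(big, rep(c("a", "b"), 100), scheme = "leave_one_out"),
    "stratified_kfold"
  )

  evk <- repeated_cv_evaluate(d$X, d$y, repeats = 1L,
                              scheme = "stratified_kfold", folds = 4L,
                              seed = 3L, learning_curve = TRUE,
                              curve_fractions = c(0.6, 1))
  expect_equal(nrow(evk$curve), 2L)
  expect_true(all(evk$curve$n <= nrow(d$X)))
})
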