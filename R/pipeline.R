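#' Pipeline run configuration
#'
#' One configuration object drives the whole pipeline. `mode` selects how
#' the data-dependent fit stages are scoped:
#' * `leakage_safe` (default): the normative reference, imputation medians,
#'   scaler and feature selection are fitted on the training partition only;
#'   both partitions are imputed with the pooled training medians, the same
#'   transform a deployed classifier could apply to an unlabeled subject
#'   (test labels are sealed). Class-conditional imputation of the training
#'   partition is deliberately avoided: filling training gaps with
#'   class-specific values while test gaps get pooled ones makes the
#'   selection stage favor features that survive only the label-aware fill.
#' * `paper_mode`: mirrors the published retrospective ordering -- the
#'   normative reference, imputation (class-conditional, using true
#'   labels), scaling and selection are computed on the whole cohort before
#'   the split.
#'
#' @param cohort a [cohort_config()] describing the synthetic cohort, or an
#'   existing [gait_cohort()]
#' @param registry planted-effect registry for simulation
#' @param mode `"leakage_safe"` or `"paper_mode"`
#' @param split_ratio held-out test fraction
#' @param hyperparameters ensemble hyperparameters, or `"tune"` to run the
#'   randomized/grid searches, or `"paper"` for the published preset
#' @param tune_budget randomized-search draws per algorithm when tuning
#' @param vote_budget sampled weight vectors for the soft-vote optimization
#' @param selection_folds,selection_trees,selection_size_grid selection
#'   stage settings (see [select_features()])
#' @param explain_n_samples LIME perturbations per subject
#' @param explain_subjects subjects sampled per condition for aggregation
#' @param explain_top_k features reported per (condition, model)
#' @param log_features enable the optional natural-log feature transform
#' @param seeds named list of stage seeds (`simulation`, `split`, `tuning`,
#'   `models`, `voting`, `lime`, `selection`); absent entries derive from
#'   `seed`
#' @param seed master seed used to derive absent stage seeds
#' @return Object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       registry = condition_effect_registry(),
                       mode = c("leakage_safe", "paper_mode"),
                       split_ratio = 0.15,
                       hyperparameters = default_hyperparameters(),
                       tune_budget = 10L,
                       vote_budget = 200L,
                       selection_folds = 5L,
                       selection_trees = 500L,
                       selection_size_grid = NULL,
                       explain_n_samples = 1000L,
                       explain_subjects = 20L,
                       explain_top_k = 5L,
                       log_features = FALSE,
                       seeds = list(),
                       seed = 1L) {
  mode <- match.arg(mode)
  stage_names <- c("simulation", "split", "tuning", "models", "voting",
                   "lime", "selection")
  full <- stats::setNames(
    lapply(seq_along(stage_names), function(i) child_seed(seed, 1000L + i)),
    stage_names
  )
  for (nm in intersect(names(seeds), stage_names)) full[[nm]] <- seeds[[nm]]
  structure(
    list(cohort = cohort, registry = registry, mode = mode,
         split_ratio = split_ratio, hyperparameters = hyperparameters,
         tune_budget = tune_budget, vote_budget = vote_budget,
         selection_folds = selection_folds, selection_trees = selection_trees,
         selection_size_grid = selection_size_grid,
         explain_n_samples = explain_n_samples,
         explain_subjects = explain_subjects, explain_top_k = explain_top_k,
         log_features = log_features, seeds = full, seed = as.integer(seed)),
    class = "run_config"
  )
}

# Sealed test labels: stages receive the vault, not the labels; every
# access is recorded with its purpose so leakage is auditable.
label_vault <- function(labels) {
  log <- character(0)
  list(
    get = function(purpose) {
      log <<- c(log, purpose)
      labels
    },
    accesses = function() log
  )
}

#' Run the full pipeline
#'
#' Simulate (when given a [cohort_config()]) -> impute -> normative ->
#' derive + extract features -> optional log transform -> scale -> select ->
#' split -> (tune) -> train -> optimize vote weights -> evaluate -> explain.
#' In `leakage_safe` mode every data-dependent fit uses the training
#' partition only and the test labels sit in a sealed vault opened exactly
#' once, by the evaluation stage.
#'
#' @param config a [run_config()]
#' @param out_dir optional directory; when given, artifacts (cohort CSV,
#'   normative CSV, feature table, selection report, metrics JSON, relevance
#'   report) are written there
#' @param stages which stages to run after training; `"explain"` may be
#'   dropped for speed
#' @return Object of class `pipeline_result` with the cohort, feature
#'   tables, selection result, fitted [gait_ensemble()], test metrics,
#'   relevance table, and the label-vault access log.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         stages = c("evaluate", "explain")) {
  stopifnot(inherits(config, "run_config"))
  seeds <- config$seeds
  # --- simulate -----------------------------------------------------------
  cohort <- if (inherits(config$cohort, "gait_cohort")) config$cohort else {
    cc <- config$cohort
    cc$seed <- as.integer(seeds$simulation)
    generate_cohort(cc, config$registry)
  }
  labels_all <- cohort_labels(cohort)
  ids_all <- cohort_ids(cohort)
  paper_mode <- config$mode == "paper_mode"

  # --- split at subject level --------------------------------------------
  split <- stratified_split(
    data.frame(subject_id = ids_all, condition = labels_all,
               stringsAsFactors = FALSE),
    ratio = config$split_ratio, seed = seeds$split
  )
  test_labels <- stats::setNames(labels_all[match(split$test_ids, ids_all)],
                                 split$test_ids)
  vault <- label_vault(test_labels)

  engineer <- function(fit_cohort, all_cohort, impute_mode_train, impute_mode_test) {
    imputer <- fit_imputer(fit_cohort)
    train_ids <- cohort_ids(fit_cohort)
    imputed <- apply_imputer(subset_cohort(all_cohort, train_ids), imputer,
                             mode = impute_mode_train)
    rest_ids <- setdiff(cohort_ids(all_cohort), train_ids)
    if (length(rest_ids) > 0L) {
      rest <- apply_imputer(subset_cohort(all_cohort, rest_ids), imputer,
                            mode = impute_mode_test)
      imputed <- gait_cohort(c(imputed$subjects, rest$subjects),
                             provenance = all_cohort$provenance)
    }
    imputed <- subset_cohort(imputed, cohort_ids(all_cohort))
    normative <- compute_normative(subset_cohort(imputed, train_ids))
    features <- extract_cohort_features(imputed, normative)
    features <- log_transform(features, enabled = config$log_features)
    scaler <- fit_scaler(features[features$subject_id %in% train_ids, ])
    list(imputer = imputer, normative = normative, features = features,
         scaler = scaler, imputed = imputed)
  }

  if (paper_mode) {
    eng <- engineer(cohort, cohort, "class_conditional", "class_conditional")
  } else {
    train_cohort <- subset_cohort(cohort, split$train_ids)
    eng <- engineer(train_cohort, cohort, "pooled", "pooled")
  }
  features <- eng$features
  scaled <- apply_scaler(features, eng$scaler)

  train_tab <- scaled[scaled$subject_id %in% split$train_ids, ]
  test_tab <- scaled[scaled$subject_id %in% split$test_ids, ]

  # --- selection ----------------------------------------------------------
  sel_tab <- if (paper_mode) scaled else train_tab
  fm <- feature_matrix(sel_tab)
  selection <- select_features(
    fm$X, fm$y, cv_folds = config$selection_folds, seed = seeds$selection,
    size_grid = config$selection_size_grid, n_trees = config$selection_trees
  )
  feats <- selection$final_subset

  # --- hyperparameters ----------------------------------------------------
  tr <- feature_matrix(train_tab, feats)
  hp <- config$hyperparameters
  if (identical(hp, "paper")) hp <- paper_preset("all")
  if (identical(hp, "tune")) {
    hp <- lapply(stats::setNames(c("svm", "rf", "lregr", "knn"),
                                 c("svm", "rf", "lregr", "knn")),
                 function(a) {
      tune_hyperparameters(a, tr$X, as.character(tr$y),
                           budget = config$tune_budget, seed = seeds$tuning)
    })
  }

  # --- train + vote -------------------------------------------------------
  bundle <- train_bundle(tr$X, as.character(tr$y), hp, seed = seeds$models)
  bundle <- optimize_vote_weights(bundle, tr$X, as.character(tr$y),
                                  budget = config$vote_budget,
                                  seed = seeds$voting)

  # --- evaluate -----------------------------------------------------------
  metrics <- NULL
  per_model_metrics <- NULL
  if ("evaluate" %in% stages) {
    te <- feature_matrix(test_tab, feats)
    y_test <- as.character(vault$get("evaluation")[test_tab$subject_id])
    pred <- predict_soft_vote(bundle, te$X)
    metrics <- metrics_report(y_test, pred$labels)
    per_model_metrics <- lapply(bundle$models, function(m) {
      p <- predict_prob(m, te$X)
      metrics_report(y_test, colnames(p)[max.col(p, ties.method = "first")])
    })
  }

  # --- explain ------------------------------------------------------------
  relevance <- NULL
  if ("explain" %in% stages) {
    orig_train <- features[features$subject_id %in% split$train_ids, ]
    background <- orig_train[, feats, drop = FALSE]
    # subjects sampled from the full cohort per condition, explained at
    # their true label
    expl_ids <- character(0)
    for (cond in sort(unique(labels_all))) {
      cond_ids <- ids_all[labels_all == cond]
      take <- min(config$explain_subjects, length(cond_ids))
      expl_ids <- c(expl_ids, with_seed(
        child_seed(seeds$lime, nchar(cond) + length(expl_ids)),
        sample(cond_ids, take)
      ))
    }
    explanations <- lapply(stats::setNames(expl_ids, expl_ids), function(id) {
      xrow <- features[features$subject_id == id, feats, drop = FALSE]
      explain_subject(
        bundle, eng$scaler, background,
        stats::setNames(as.numeric(xrow[1, ]), feats),
        target_class = labels_all[match(id, ids_all)],
        n_samples = config$explain_n_samples,
        seed = child_seed(seeds$lime, match(id, ids_all)),
        n_features = max(10L, config$explain_top_k)
      )
    })
    relevance <- aggregate_top_features(
      explanations, stats::setNames(labels_all, ids_all),
      k = config$explain_top_k, n_subjects = config$explain_subjects,
      seed = seeds$lime
    )
  }

  result <- structure(
    list(config = config, cohort = cohort, split = split,
         normative = eng$normative, features = features, scaler = eng$scaler,
         selection = selection, hyperparameters = hp, bundle = bundle,
         metrics = metrics, per_model_metrics = per_model_metrics,
         relevance = relevance, vault_log = vault$accesses()),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) write_artifacts(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline run (%s mode, seed %d)\n", x$config$mode, x$config$seed))
  cat(sprintf("  cohort: %d subjects; selected features: %d\n",
              length(x$cohort$subjects), length(x$selection$final_subset)))
  if (!is.null(x$metrics)) {
    m <- x$metrics[x$metrics$class == "macro", ]
    cat(sprintf("  MV test macro: BA=%.3f recall=%.3f precision=%.3f F1=%.3f\n",
                m$balanced_accuracy, m$recall, m$precision, m$f1))
  }
  invisible(x)
}

#' Serialize test metrics as canonical JSON
#'
#' Per-class and macro metrics for the soft vote and each member model;
#' byte-stable for identical inputs, so reruns with identical configuration
#' and seeds produce byte-identical files.
#'
#' @param result a [run_pipeline()] result
#' @param path output path
#' @return `path` invisibly.
#' @export
write_metrics_json <- function(result, path) {
  stopifnot(inherits(result, "pipeline_result"))
  pack <- function(rep) {
    lapply(seq_len(nrow(rep)), function(i) {
      list(class = rep$class[i],
           balanced_accuracy = round(rep$balanced_accuracy[i], 10),
           recall = round(rep$recall[i], 10),
           precision = round(rep$precision[i], 10),
           f1 = round(rep$f1[i], 10))
    })
  }
  payload <- list(
    mode = result$config$mode, seed = result$config$seed,
    n_selected_features = length(result$selection$final_subset),
    mv = pack(result$metrics)
  )
  for (m in names(result$per_model_metrics)) {
    payload[[m]] <- pack(result$per_model_metrics[[m]])
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

write_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(result$cohort, file.path(out_dir, "cohort.csv"))
  write_normative(result$normative, file.path(out_dir, "normative.csv"))
  write_feature_table(result$features, file.path(out_dir, "features.csv"))
  jsonlite::write_json(
    list(rfe_subset = result$selection$rfe_subset,
         importance_subset = result$selection$importance_subset,
         final_subset = result$selection$final_subset,
         rfe_score_trace = result$selection$rfe_score_trace),
    file.path(out_dir, "selection.json"), auto_unbox = TRUE, digits = NA
  )
  if (!is.null(result$metrics)) {
    write_metrics_json(result, file.path(out_dir, "metrics.json"))
  }
  if (!is.null(result$relevance)) {
    relevance_report(result$relevance,
                     json_path = file.path(out_dir, "relevance.json"),
                     txt_path = file.path(out_dir, "relevance.txt"))
  }
  invisible(out_dir)
}
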