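#' Fit a median imputation model on a training cohort
#'
#' For every grid cell (angle, series kind, grid index k) the model stores
#' the median of the observed values, both per condition (class medians) and
#' pooled over all training subjects. Medians use the standard convention:
#' the mean of the two middle order statistics for even counts. A class
#' median that has no observed values at a cell falls back to the pooled
#' median at application time.
#'
#' @param cohort training [gait_cohort()]
#' @return Object of class `imputation_model`.
#' @export
fit_imputer <- function(cohort) {
  stopifnot(inherits(cohort, "gait_cohort"))
  if (length(cohort$subjects) == 0L) stop("training cohort is empty", call. = FALSE)
  labs <- cohort_labels(cohort)
  classes <- unique(labs)
  # per angle/kind: matrix n_points x n_subjects
  stack <- function(subjects, a, kind) {
    vapply(subjects, function(s) s$angles[[a]][[kind]], numeric(GRID_N))
  }
  pooled <- list(); class_med <- list()
  for (a in gait_angles()) {
    for (kind in c("mean", "std")) {
      m <- stack(cohort$subjects, a, kind)
      pm <- apply(m, 1L, stats::median, na.rm = TRUE)
      if (anyNA(pm)) {
        k_bad <- which(is.na(pm))[1L] - 1L
        stop(sprintf("cell never observed in training: %s %s k=%d", a, kind, k_bad),
             call. = FALSE)
      }
      pooled[[paste(a, kind, sep = "|")]] <- pm
      for (cl in classes) {
        mc <- m[, labs == cl, drop = FALSE]
        cm <- suppressWarnings(apply(mc, 1L, stats::median, na.rm = TRUE))
        class_med[[paste(cl, a, kind, sep = "|")]] <- cm  # may contain NA
      }
    }
  }
  structure(list(pooled = pooled, class_medians = class_med, classes = classes),
            class = "imputation_model")
}

#' Apply a median imputation model
#'
#' Fills every missing grid cell. In `class_conditional` mode (training
#' data) the median of the subject's own condition is used, falling back to
#' the pooled median where the class never observed the cell; in `pooled`
#' mode (the default for unlabeled test data) class labels are ignored.
#' Observed values are never altered.
#'
#' @param cohort a [gait_cohort()]
#' @param model a fitted [fit_imputer()] model
#' @param mode `"class_conditional"` or `"pooled"`
#' @return The cohort with no missing cells.
#' @export
apply_imputer <- function(cohort, model, mode = c("pooled", "class_conditional")) {
  stopifnot(inherits(cohort, "gait_cohort"), inherits(model, "imputation_model"))
  mode <- match.arg(mode)
  for (i in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[i]]
    if (mode == "class_conditional" &&
        (is.null(s$condition) || is.na(s$condition) || !nzchar(s$condition))) {
      stop("class_conditional imputation requested on unlabeled data", call. = FALSE)
    }
    for (a in gait_angles()) {
      for (kind in c("mean", "std")) {
        ser <- s$angles[[a]][[kind]]
        miss <- which(is.na(ser))
        if (length(miss) == 0L) next
        fill <- model$pooled[[paste(a, kind, sep = "|")]]
        if (mode == "class_conditional") {
          cm <- model$class_medians[[paste(s$condition, a, kind, sep = "|")]]
          if (!is.null(cm)) {
            ok <- !is.na(cm)
            fill[ok] <- cm[ok]
          }
        }
        ser[miss] <- fill[miss]
        cohort$subjects[[i]]$angles[[a]][[kind]] <- ser
      }
    }
  }
  cohort
}

#' Min-max feature scaling
#'
#' `fit_scaler` learns per-feature training minima and maxima;
#' `apply_scaler` maps `x` to `(x - min) / (max - min)`. Constant training
#' features map to 0 and are flagged. Test values outside the training range
#' are not clipped and may fall outside `[0, 1]`. `invert_scaler` undoes the
#' scaling for non-constant features, e.g. to report explanations in
#' original units.
#'
#' @param table feature table (data.frame with canonical feature columns)
#' @param features which feature columns to scale (default: all canonical
#'   ones present in the table)
#' @return `fit_scaler`: object of class `scaler_params` with per-feature
#'   `min`, `max` and a constant-feature flag.
#' @export
fit_scaler <- function(table, features = NULL) {
  feats <- features %||% intersect(enumerate_feature_names(), names(table))
  if (nrow(table) == 0L || length(feats) == 0L) {
    stop("cannot fit a scaler on an empty table", call. = FALSE)
  }
  mins <- vapply(feats, function(f) min(table[[f]], na.rm = TRUE), numeric(1))
  maxs <- vapply(feats, function(f) max(table[[f]], na.rm = TRUE), numeric(1))
  structure(list(features = feats, min = mins, max = maxs,
                 constant = maxs == mins),
            class = "scaler_params")
}

#' @rdname fit_scaler
#' @param params a fitted `scaler_params`
#' @export
apply_scaler <- function(table, params) {
  stopifnot(inherits(params, "scaler_params"))
  absent <- setdiff(params$features, names(table))
  if (length(absent) > 0L) {
    stop("table lacks scaled column(s): ", paste(utils::head(absent, 3), collapse = ", "),
         call. = FALSE)
  }
  for (f in params$features) {
    if (params$constant[[f]]) {
      table[[f]] <- rep(0, nrow(table))
    } else {
      table[[f]] <- (table[[f]] - params$min[[f]]) / (params$max[[f]] - params$min[[f]])
    }
  }
  table
}

#' @rdname fit_scaler
#' @export
invert_scaler <- function(table, params) {
  stopifnot(inherits(params, "scaler_params"))
  for (f in params$features) {
    if (params$constant[[f]]) {
      table[[f]] <- rep(params$min[[f]], nrow(table))
    } else {
      table[[f]] <- table[[f]] * (params$max[[f]] - params$min[[f]]) + params$min[[f]]
    }
  }
  table
}

# restrict a fitted scaler to a feature subset
subset_scaler <- function(params, features) {
  absent <- setdiff(features, params$features)
  if (length(absent) > 0L) {
    stop("scaler does not cover: ", paste(utils::head(absent, 3), collapse = ", "),
         call. = FALSE)
  }
  structure(list(features = features, min = params$min[features],
                 max = params$max[features], constant = params$constant[features]),
            class = "scaler_params")
}

#' Optional natural-log transform of feature columns
#'
#' Disabled by default: skewing the inputs toward normality brought no
#' measurable benefit, so the transform is retained only as an option. When
#' enabled, each column is first shifted to be strictly positive
#' (`shift = 1 - min` if the minimum is nonpositive) and then log-transformed,
#' which is monotone per column.
#'
#' @param table feature table
#' @param enabled logical flag
#' @param features columns to transform (default: canonical features present)
#' @return The (possibly transformed) table.
#' @export
log_transform <- function(table, enabled = FALSE, features = NULL) {
  if (!enabled) return(table)
  feats <- features %||% intersect(enumerate_feature_names(), names(table))
  for (f in feats) {
    x <- table[[f]]
    mn <- min(x, na.rm = TRUE)
    shift <- if (mn <= 0) 1 - mn else 0
    table[[f]] <- log(x + shift)
  }
  table
}
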