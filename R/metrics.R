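#' One-vs-rest confusion counts for one class
#'
#' @param y_true true labels
#' @param y_pred predicted labels (same length)
#' @param class the positive class
#' @return Named numeric vector `(TP, TN, FP, FN)`; the four counts sum
#'   to `length(y_true)`.
#' @export
confusion_counts <- function(y_true, y_pred, class) {
  if (length(y_true) != length(y_pred)) {
    stop("label vectors differ in length", call. = FALSE)
  }
  if (!class %in% c(as.character(y_true), as.character(y_pred))) {
    stop("unknown class: ", class, call. = FALSE)
  }
  tp <- sum(y_true == class & y_pred == class)
  tn <- sum(y_true != class & y_pred != class)
  fp <- sum(y_true != class & y_pred == class)
  fn <- sum(y_true == class & y_pred != class)
  c(TP = tp, TN = tn, FP = fp, FN = fn)
}

#' Per-class and macro classification metrics
#'
#' One-vs-rest metrics per class from the confusion counts:
#' balanced accuracy `(TP/(TP+FN) + TN/(TN+FP)) / 2`, recall `TP/(TP+FN)`,
#' precision `TP/(TP+FP)`, and F1 `2 * precision * recall /
#' (precision + recall)`. Ratios with a zero denominator are reported as 0
#' and flagged. The macro row is the unweighted mean over classes.
#'
#' @param y_true true labels
#' @param y_pred predicted labels
#' @return Object of class `metrics_report`: data.frame with one row per
#'   class plus a `"macro"` row, columns `balanced_accuracy`, `recall`,
#'   `precision`, `f1`, the four confusion counts, and a `degenerate` flag.
#' @export
metrics_report <- function(y_true, y_pred) {
  if (length(y_true) == 0L) stop("empty label vectors", call. = FALSE)
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  classes <- sort(unique(c(y_true, y_pred)))
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  rows <- lapply(classes, function(cl) {
    cc <- confusion_counts(y_true, y_pred, cl)
    rec <- safe_div(cc[["TP"]], cc[["TP"]] + cc[["FN"]])
    spec <- safe_div(cc[["TN"]], cc[["TN"]] + cc[["FP"]])
    prec <- safe_div(cc[["TP"]], cc[["TP"]] + cc[["FP"]])
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    degen <- (cc[["TP"]] + cc[["FN"]] == 0) || (cc[["TN"]] + cc[["FP"]] == 0) ||
      (cc[["TP"]] + cc[["FP"]] == 0)
    data.frame(class = cl, balanced_accuracy = (rec + spec) / 2,
               recall = rec, precision = prec, f1 = f1,
               TP = cc[["TP"]], TN = cc[["TN"]], FP = cc[["FP"]], FN = cc[["FN"]],
               degenerate = degen, stringsAsFactors = FALSE)
  })
  per_class <- do.call(rbind, rows)
  macro <- data.frame(
    class = "macro",
    balanced_accuracy = mean(per_class$balanced_accuracy),
    recall = mean(per_class$recall),
    precision = mean(per_class$precision),
    f1 = mean(per_class$f1),
    TP = sum(per_class$TP), TN = sum(per_class$TN),
    FP = sum(per_class$FP), FN = sum(per_class$FN),
    degenerate = any(per_class$degenerate), stringsAsFactors = FALSE
  )
  structure(rbind(per_class, macro), class = c("metrics_report", "data.frame"))
}

#' @export
print.metrics_report <- function(x, digits = 3, ...) {
  cat("Classification metrics (one-vs-rest per class; macro = unweighted mean)\n")
  df <- as.data.frame(x)
  df[c("balanced_accuracy", "recall", "precision", "f1")] <-
    lapply(df[c("balanced_accuracy", "recall", "precision", "f1")], round, digits)
  print(df[, c("class", "balanced_accuracy", "recall", "precision", "f1")],
        row.names = FALSE)
  invisible(x)
}

#' Macro balanced accuracy of a labeling
#'
#' Convenience accessor used as the scoring function throughout the
#' selection, tuning and voting stages.
#'
#' @param y_true true labels
#' @param y_pred predicted labels
#' @return Scalar in `[0, 1]`.
#' @export
macro_balanced_accuracy <- function(y_true, y_pred) {
  rep <- metrics_report(y_true, y_pred)
  rep$balanced_accuracy[rep$class == "macro"]
}
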