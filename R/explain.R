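#' Local surrogate (LIME) explanation for one subject
#'
#' Perturbation-based local attribution: perturbed instances are drawn
#' per-feature from the quartile bins of the background (training) data,
#' weighted by an exponential kernel on their standardized distance to the
#' explained instance, and a weighted ridge surrogate is fitted to the
#' model's probability for the target class. The surrogate is sparsified to
#' the `n_features` largest-weight features; its signed weights are the
#' explanation. Background and instance are supplied in original units --
#' any scaling the classifier needs is composed inside `predict_fun` -- so
#' the weights read directly in degrees or % cycle.
#'
#' Constant background features cannot be perturbed; they are excluded and
#' listed in the result.
#'
#' @param predict_fun function(matrix) -> probability of the target class
#'   (numeric vector); typically wraps a [gait_ensemble()] member or the
#'   soft vote composed with [apply_scaler()]
#' @param background matrix/data.frame of training features in original units
#' @param x the instance to explain (named numeric vector, original units)
#' @param n_samples number of perturbed instances
#' @param seed integer seed; equal seeds give identical explanations
#' @param kernel_width proximity-kernel width; default `0.75 * sqrt(d)`
#'   on the standardized scale
#' @param n_features surrogate sparsity (number of nonzero weights)
#' @return Object of class `lime_explanation`: list with `weights` (named,
#'   signed; zero outside the sparse support), `intercept`, `selected`,
#'   `excluded_constant`, `n_samples`, `seed`.
#' @export
lime_explain <- function(predict_fun, background, x, n_samples = 1000L,
                         seed = 1L, kernel_width = NULL, n_features = 10L) {
  smp <- lime_sample(background, x, n_samples, seed, kernel_width)
  pz <- predict_fun(smp$Zfull)
  if (length(pz) != n_samples) stop("predict_fun must return one probability per row",
                                    call. = FALSE)
  lime_surrogate(smp, pz, n_features)
}

# draw the shared perturbation sample around x: quartile-bin sampling plus
# exponential proximity weights on the standardized scale
lime_sample <- function(background, x, n_samples, seed, kernel_width = NULL) {
  B <- as.matrix(background)
  feats <- colnames(B)
  if (is.null(feats)) stop("background must have column names", call. = FALSE)
  x <- x[feats]
  sds <- apply(B, 2L, stats::sd)
  constant <- sds == 0 | !is.finite(sds)
  use <- feats[!constant]
  if (length(use) == 0L) stop("all background features are constant", call. = FALSE)
  d <- length(use)
  if (is.null(kernel_width)) kernel_width <- 0.75 * sqrt(d)
  edges <- lapply(use, function(f) {
    q <- unique(stats::quantile(B[, f], probs = c(0, 0.25, 0.5, 0.75, 1),
                                names = FALSE))
    if (length(q) < 2L) range(B[, f]) else q
  })
  names(edges) <- use
  Z <- with_seed(seed, {
    cols <- lapply(use, function(f) {
      e <- edges[[f]]
      nb <- length(e) - 1L
      bin <- sample.int(nb, n_samples, replace = TRUE)
      stats::runif(n_samples, min = e[bin], max = e[bin + 1L])
    })
    do.call(cbind, cols)
  })
  colnames(Z) <- use
  Z[1L, ] <- x[use]  # the instance itself anchors the local fit
  # full-width matrix for the model (constant features pinned at x)
  Zfull <- matrix(rep(as.numeric(x), each = n_samples), nrow = n_samples,
                  dimnames = list(NULL, feats))
  Zfull[, use] <- Z
  Zs <- sweep(sweep(Z, 2L, x[use]), 2L, sds[use], "/")
  kw <- exp(-rowSums(Zs^2) / kernel_width^2)
  list(Z = Z, Zfull = Zfull, kw = kw, use = use, feats = feats,
       constant = constant, sds = sds, n_samples = as.integer(n_samples),
       seed = as.integer(seed), kernel_width = kernel_width)
}

# weighted ridge on standardized features to pick the sparse support, then
# a weighted least-squares refit in original units
lime_surrogate <- function(smp, pz, n_features) {
  use <- smp$use; Z <- smp$Z; kw <- smp$kw
  d <- length(use)
  Zc <- sweep(sweep(Z, 2L, colMeans(Z)), 2L, smp$sds[use], "/")
  sw <- sqrt(kw)
  A <- Zc * sw
  b <- (pz - stats::weighted.mean(pz, kw)) * sw
  beta_std <- solve(crossprod(A) + 1e-3 * diag(d), crossprod(A, b))
  keep <- order(abs(beta_std), decreasing = TRUE)[seq_len(min(n_features, d))]
  Zk <- cbind(1, Z[, keep, drop = FALSE])
  coef <- solve(crossprod(Zk * kw, Zk) + 1e-8 * diag(ncol(Zk)),
                crossprod(Zk * kw, pz))
  weights <- stats::setNames(numeric(length(smp$feats)), smp$feats)
  weights[use[keep]] <- coef[-1L]
  structure(
    list(weights = weights, intercept = coef[1L],
         selected = use[keep], excluded_constant = smp$feats[smp$constant],
         n_samples = smp$n_samples, seed = smp$seed,
         kernel_width = smp$kernel_width),
    class = "lime_explanation"
  )
}

#' @export
print.lime_explanation <- function(x, n = 5L, ...) {
  cat(sprintf("LIME explanation (%d perturbations)\n", x$n_samples))
  w <- x$weights[x$selected]
  w <- w[order(abs(w), decreasing = TRUE)]
  for (i in seq_len(min(n, length(w)))) {
    cat(sprintf("  %+.4g  %s\n", w[i], feature_label(names(w)[i])))
  }
  invisible(x)
}

#' Explain one subject with every ensemble member and the soft vote
#'
#' Convenience wrapper: builds the scaled-prediction closures for the four
#' base models and the weighted vote, targets the given class, and runs
#' [lime_explain()] for each with a shared perturbation seed so the five
#' explanations are comparable.
#'
#' @param bundle a fitted [gait_ensemble()]
#' @param scaler the [fit_scaler()] params the bundle was trained under
#' @param background training feature table in original units
#' @param x instance (named numeric vector, original units)
#' @param target_class the class whose probability is explained
#' @param n_samples,seed,n_features passed to [lime_explain()]
#' @return Named list of `lime_explanation` (svm, rf, lregr, knn, mv).
#' @export
explain_subject <- function(bundle, scaler, background, x, target_class,
                            n_samples = 1000L, seed = 1L, n_features = 10L) {
  stopifnot(inherits(bundle, "gait_ensemble"))
  feats <- bundle$feature_names
  Bmat <- as.matrix(background[, feats, drop = FALSE])
  sc <- subset_scaler(scaler, feats)
  # one shared perturbation sample: each member is predicted once and the
  # soft vote reuses the members' probabilities
  smp <- lime_sample(Bmat, x[feats], n_samples, seed)
  Zs <- as.matrix(apply_scaler(as.data.frame(smp$Zfull, check.names = FALSE),
                               sc)[, feats, drop = FALSE])
  member_p <- lapply(bundle$models, function(m) {
    predict_prob(m, Zs)[, target_class]
  })
  member_p$mv <- as.numeric(
    Reduce(`+`, Map(`*`, member_p[names(bundle$models)],
                    as.numeric(bundle$weights)))
  )
  lapply(member_p, function(pz) lime_surrogate(smp, pz, n_features))
}

#' Aggregate explanations into per-condition top-feature tables
#'
#' For each condition, `n_subjects` subjects are sampled without replacement
#' (all of them when fewer are available); per model, features are ranked by
#' the mean absolute explanation weight across the sampled subjects and the
#' top `k` are reported, together with how many sampled subjects carry the
#' feature in their own top-`k` -- the "bar length". Mean-weight ties break
#' by canonical feature order.
#'
#' @param explanations nested list: `explanations[[subject_id]][[model]]`
#'   is a `lime_explanation`; subject ids map to conditions via `conditions`
#' @param conditions named character vector subject_id -> condition label
#' @param k features reported per (condition, model)
#' @param n_subjects subjects sampled per condition
#' @param seed integer sampling seed
#' @return Object of class `relevance_table`: data.frame with columns
#'   `condition`, `model`, `rank`, `feature`, `mean_abs_weight`,
#'   `subject_count`, `n_sampled`.
#' @export
aggregate_top_features <- function(explanations, conditions, k = 5L,
                                   n_subjects = 20L, seed = 1L) {
  ids <- names(explanations)
  if (length(ids) == 0L) stop("no explanations to aggregate", call. = FALSE)
  canon <- enumerate_feature_names()
  rows <- list()
  for (cond in sort(unique(conditions[ids]))) {
    cond_ids <- ids[conditions[ids] == cond]
    sampled <- if (length(cond_ids) > n_subjects) {
      with_seed(child_seed(seed, which(sort(unique(conditions[ids])) == cond)),
                sample(cond_ids, n_subjects))
    } else cond_ids
    models <- names(explanations[[sampled[1L]]])
    for (m in models) {
      W <- vapply(sampled, function(id) {
        abs(explanations[[id]][[m]]$weights)
      }, numeric(length(explanations[[sampled[1L]]][[m]]$weights)))
      W <- matrix(W, ncol = length(sampled))
      rownames(W) <- names(explanations[[sampled[1L]]][[m]]$weights)
      mean_abs <- rowMeans(W)
      # per-subject top-k membership counts
      counts <- rowSums(apply(W, 2L, function(col) {
        top <- order(col, decreasing = TRUE)[seq_len(min(k, length(col)))]
        seq_along(col) %in% top
      }))
      ord <- order(-mean_abs, match(names(mean_abs), canon))
      top <- ord[seq_len(min(k, length(ord)))]
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, model = m, rank = seq_along(top),
        feature = names(mean_abs)[top], mean_abs_weight = mean_abs[top],
        subject_count = counts[top], n_sampled = length(sampled),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("relevance_table", "data.frame"))
}

#' @export
print.relevance_table <- function(x, ...) {
  cat("Per-condition top explanation features\n")
  df <- as.data.frame(x)
  df$feature <- feature_label(df$feature)
  df$mean_abs_weight <- signif(df$mean_abs_weight, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Relevance report across models
#'
#' Merges a [aggregate_top_features()] table into the per-condition union of
#' each model's top features, with one subject-count column per model (the
#' bar-length analog), feature names decoded to prose. Optionally written as
#' JSON and a plain-text table.
#'
#' @param table a `relevance_table`
#' @param json_path optional output path for the JSON report
#' @param txt_path optional output path for the text table
#' @return data.frame with columns `condition`, `feature`, `label`, and one
#'   count column per model.
#' @export
relevance_report <- function(table, json_path = NULL, txt_path = NULL) {
  models <- unique(table$model)
  out <- list()
  for (cond in unique(table$condition)) {
    sub <- table[table$condition == cond, ]
    feats <- unique(sub$feature)
    row <- data.frame(condition = cond, feature = feats,
                      label = feature_label(feats), stringsAsFactors = FALSE)
    for (m in models) {
      cnt <- integer(length(feats))
      sm <- sub[sub$model == m, ]
      cnt[match(sm$feature, feats)] <- sm$subject_count
      row[[paste0("count_", m)]] <- cnt
    }
    out[[length(out) + 1L]] <- row
  }
  rep <- do.call(rbind, out)
  rownames(rep) <- NULL
  if (!is.null(json_path)) {
    jsonlite::write_json(rep, json_path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  }
  if (!is.null(txt_path)) {
    con <- file(txt_path, "w")
    on.exit(close(con))
    for (cond in unique(rep$condition)) {
      writeLines(c(cond, strrep("-", nchar(cond))), con)
      sub <- rep[rep$condition == cond, ]
      for (i in seq_len(nrow(sub))) {
        counts <- paste(vapply(models, function(m) {
          sprintf("%s=%d", m, sub[[paste0("count_", m)]][i])
        }, character(1)), collapse = " ")
        writeLines(sprintf("  %-70s %s", sub$label[i], counts), con)
      }
      writeLines("", con)
    }
  }
  rep
}
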