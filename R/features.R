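#' Segment the gait cycle into stance and swing
#'
#' The boundary index is `r = round-half-up(foot_off_mean)`; stance covers
#' grid indices `[0, r]` and swing `[r, 100]`. The boundary index belongs to
#' both phases: the foot-off instant ends stance and starts swing, which
#' keeps both windows nonempty for any admissible foot-off.
#'
#' @param foot_off_mean foot-off instant, % gait cycle, strictly in (0, 100)
#' @return Object of class `phase_windows`: list with integer index vectors
#'   `stance`, `swing`, `full` (grid indices, 0-based) and the boundary `r`.
#' @export
segment_phases <- function(foot_off_mean) {
  if (!is.finite(foot_off_mean) || foot_off_mean <= 0 || foot_off_mean >= 100) {
    stop("foot_off_mean must lie strictly inside (0, 100)", call. = FALSE)
  }
  r <- as.integer(round_half_up(foot_off_mean))
  if (r <= 0L || r >= 100L) {
    stop("foot-off rounds to a degenerate boundary index", call. = FALSE)
  }
  structure(list(stance = 0:r, swing = r:100, full = 0:100, r = r),
            class = "phase_windows")
}

# statistics of one series over one window; `domain` gives the grid indices
# the series is defined on (0..100 for mean/std/diff_norm, 1..99 for the
# first gradient). Timings are reported in % gait cycle; extremum ties go to
# the earliest occurrence.
window_stats <- function(series, domain, window) {
  keep <- domain %in% window
  if (!any(keep)) stop("empty window after domain intersection", call. = FALSE)
  s <- series[keep]
  g <- domain[keep]
  i_max <- which.max(s)
  i_min <- which.min(s)
  list(max = s[i_max], timing_max = g[i_max],
       min = s[i_min], timing_min = g[i_min],
       avg = mean(s))
}

#' Extract the 374-feature vector for one subject
#'
#' Per angle and per phase (stance/swing): extrema and their timings of the
#' mean, first-gradient and difference-from-normative series; max and its
#' timing of the std series; the window-averaged difference from normative;
#' plus the full-cycle range of motion of the mean series. Gradient windows
#' are intersected with the interior grid 1..99. The two foot-off scalars
#' are copied from the record.
#'
#' @param subject a [subject_record()] (imputed)
#' @param derived the subject's [derive_series()] output
#' @param windows the subject's [segment_phases()] windows
#' @return Named numeric vector in canonical [enumerate_feature_names()]
#'   order (374 entries for the 12 canonical angles).
#' @export
extract_features <- function(subject, derived, windows) {
  names_out <- enumerate_feature_names()
  out <- stats::setNames(numeric(length(names_out)), names_out)
  grid_full <- 0:100
  grid_grad <- 1:99
  for (a in gait_angles()) {
    d <- derived[[a]]
    for (ph in c("stance", "swing")) {
      w <- windows[[ph]]
      st <- window_stats(d$mean, grid_full, w)
      out[feature_name(a, "mean", ph, c("max", "timing_max", "min", "timing_min"))] <-
        c(st$max, st$timing_max, st$min, st$timing_min)
      sv <- window_stats(d$std, grid_full, w)
      out[feature_name(a, "std", ph, c("max", "timing_max"))] <- c(sv$max, sv$timing_max)
      gr <- window_stats(d$first_gradient, grid_grad, w)
      out[feature_name(a, "first_gradient", ph, c("max", "timing_max", "min", "timing_min"))] <-
        c(gr$max, gr$timing_max, gr$min, gr$timing_min)
      dn <- window_stats(d$diff_norm, grid_full, w)
      out[feature_name(a, "diff_norm", ph,
                       c("max", "timing_max", "min", "timing_min", "avg_diff_norm"))] <-
        c(dn$max, dn$timing_max, dn$min, dn$timing_min, dn$avg)
    }
    out[feature_name(a, "mean", "full", "range_of_motion")] <-
      max(d$mean) - min(d$mean)
  }
  out[feature_name("Foot_off", "mean", "full", "value")] <- subject$foot_off_mean
  out[feature_name("Foot_off", "std", "full", "value")] <- subject$foot_off_std
  out
}

#' Extract the feature table for a whole cohort
#'
#' Runs derivation, phase segmentation and feature extraction per subject
#' and assembles the wide feature table: one row per subject, the 374
#' canonical feature columns, the condition label, and `subject_id`.
#'
#' @param cohort an imputed [gait_cohort()]
#' @param normative a [compute_normative()] reference
#' @return data.frame with columns `subject_id`, the canonical features,
#'   `condition`.
#' @export
extract_cohort_features <- function(cohort, normative) {
  stopifnot(inherits(cohort, "gait_cohort"))
  canon <- enumerate_feature_names()
  if (length(cohort$subjects) == 0L) {
    empty <- as.data.frame(stats::setNames(
      c(list(character()), rep(list(numeric()), length(canon)), list(character())),
      c("subject_id", canon, "condition")
    ), check.names = FALSE, stringsAsFactors = FALSE)
    return(empty)
  }
  rows <- lapply(cohort$subjects, function(s) {
    tryCatch({
      derived <- derive_series(s, normative)
      windows <- segment_phases(s$foot_off_mean)
      extract_features(s, derived, windows)
    }, error = function(e) {
      stop(sprintf("feature extraction failed for subject %s: %s",
                   s$subject_id, conditionMessage(e)), call. = FALSE)
    })
  })
  tab <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  tab <- cbind(subject_id = cohort_ids(cohort), tab,
               condition = cohort_labels(cohort), stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  tab
}

# split a feature table into (X matrix, y factor, ids); X keeps canonical
# column order restricted to `features` when given
feature_matrix <- function(table, features = NULL) {
  canon <- enumerate_feature_names()
  keep <- if (is.null(features)) canon else {
    bad <- setdiff(features, canon)
    if (length(bad) > 0L) stop("unknown feature(s): ", paste(utils::head(bad, 3), collapse = ", "),
                               call. = FALSE)
    canon[canon %in% features]
  }
  X <- as.matrix(table[, keep, drop = FALSE])
  storage.mode(X) <- "double"
  list(X = X,
       y = if ("condition" %in% names(table)) factor(table$condition) else NULL,
       ids = table$subject_id)
}
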