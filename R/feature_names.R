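#' Feature-name encoding
#'
#' A feature name is the canonical string `"angle|series|phase|statistic"`.
#' Series is one of `mean`, `std`, `first_gradient`, `diff_norm`; phase one
#' of `stance`, `swing`, `full`; statistic one of `max`, `timing_max`,
#' `min`, `timing_min`, `avg_diff_norm`, `range_of_motion`, `value`.
#' The encoding is bijective with the (angle, series, phase, statistic)
#' tuple; [decode_feature_name()] inverts it.
#'
#' @param angle canonical angle name or `"Foot_off"`
#' @param series series kind
#' @param phase phase window
#' @param statistic scalar statistic
#' @return The canonical encoded name.
#' @export
feature_name <- function(angle, series, phase, statistic) {
  paste(angle, series, phase, statistic, sep = "|")
}

#' @rdname feature_name
#' @param name an encoded feature name (vectorized)
#' @return For `decode_feature_name`, a data.frame with columns
#'   `angle`, `series`, `phase`, `statistic`.
#' @export
decode_feature_name <- function(name) {
  parts <- strsplit(name, "|", fixed = TRUE)
  bad <- lengths(parts) != 4L
  if (any(bad)) {
    stop("malformed feature name(s): ", paste(name[bad], collapse = ", "),
         call. = FALSE)
  }
  m <- do.call(rbind, parts)
  data.frame(
    angle = m[, 1L], series = m[, 2L], phase = m[, 3L], statistic = m[, 4L],
    stringsAsFactors = FALSE
  )
}

#' Enumerate the canonical feature names
#'
#' Per angle, 31 features: 4 extremum/timing statistics of the mean series in
#' each of stance and swing plus its full-cycle range of motion (9); max and
#' timing of max of the stride-variability (std) series per phase (4); 4
#' extremum/timing statistics of the first-gradient series per phase (8); the
#' 4 extremum/timing statistics plus the window-averaged deviation of the
#' difference-from-normative series per phase (10). Two global foot-off
#' features (mean and std of the foot-off instant) complete the set, so the
#' full 12-angle enumeration has `12 * 31 + 2 = 374` names. Within a phase a
#' series carries 4 statistics except std (2) and diff_norm (5), i.e. 15
#' features per angle per phase before the range of motion.
#'
#' Order is deterministic: angles in canonical order; within an angle, series
#' in the order mean, std, first_gradient, diff_norm; within a series, phase
#' in the order stance, swing, full; statistics in the order max, timing_max,
#' min, timing_min, then avg_diff_norm or range_of_motion.
#'
#' @param angles character vector of canonical angle names
#' @return Character vector of encoded feature names, length `31 * length(angles) + 2`.
#' @export
#' @examples
#' length(enumerate_feature_names(gait_angles()))  # 374
enumerate_feature_names <- function(angles = gait_angles()) {
  if (length(angles) == 0L) stop("angles must be nonempty", call. = FALSE)
  check_angles(angles)
  ext <- c("max", "timing_max", "min", "timing_min")
  per_angle <- function(a) {
    c(
      feature_name(a, "mean", "stance", ext),
      feature_name(a, "mean", "swing", ext),
      feature_name(a, "mean", "full", "range_of_motion"),
      feature_name(a, "std", "stance", c("max", "timing_max")),
      feature_name(a, "std", "swing", c("max", "timing_max")),
      feature_name(a, "first_gradient", "stance", ext),
      feature_name(a, "first_gradient", "swing", ext),
      feature_name(a, "diff_norm", "stance", c(ext, "avg_diff_norm")),
      feature_name(a, "diff_norm", "swing", c(ext, "avg_diff_norm"))
    )
  }
  c(
    unlist(lapply(angles, per_angle), use.names = FALSE),
    feature_name("Foot_off", "mean", "full", "value"),
    feature_name("Foot_off", "std", "full", "value")
  )
}

#' Human-readable feature label
#'
#' Decodes an encoded feature name into clinical prose, e.g.
#' `"Tibiotalar flexion|first_gradient|stance|timing_min"` becomes
#' `"Timing of Min of First Gradient of Tibiotalar flexion (Stance)"`.
#'
#' @param name encoded feature name (vectorized)
#' @return Character vector of labels.
#' @export
feature_label <- function(name) {
  d <- decode_feature_name(name)
  series_txt <- c(
    mean = "", std = " |STD|",
    first_gradient = "First Gradient of ", diff_norm = "Difference from Normative of "
  )
  stat_txt <- c(
    max = "Max of", timing_max = "Timing of Max of",
    min = "Min of", timing_min = "Timing of Min of",
    avg_diff_norm = "Average", range_of_motion = "Range of Motion of",
    value = "Value of"
  )
  vapply(seq_len(nrow(d)), function(i) {
    if (d$angle[i] == "Foot_off") {
      return(sprintf("Foot off (%s)", d$series[i]))
    }
    angle <- d$angle[i]
    if (d$series[i] == "std") angle <- paste0(angle, " |STD|")
    series_prefix <- if (d$series[i] %in% c("first_gradient", "diff_norm")) {
      series_txt[[d$series[i]]]
    } else ""
    core <- if (d$statistic[i] == "avg_diff_norm") {
      sprintf("Average Difference from Normative of %s", angle)
    } else {
      sprintf("%s %s%s", stat_txt[[d$statistic[i]]], series_prefix, angle)
    }
    phase <- switch(d$phase[i],
      stance = " (Stance)", swing = " (Swing)", full = ""
    )
    paste0(core, phase)
  }, character(1))
}
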