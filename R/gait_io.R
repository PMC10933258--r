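#' Subject record
#'
#' One subject's gait profile: the 12 canonical functional angles, each with
#' a mean and a stride-variability (std) series on the 101-point gait-cycle
#' grid, the foot-off instant (mean and std, % gait cycle), a condition
#' label, and optional demographics (age yr, height cm, weight kg).
#'
#' @param subject_id unique identifier
#' @param condition condition label
#' @param foot_off_mean foot-off instant, % gait cycle, strictly in (0, 100)
#' @param foot_off_std between-stride sd of the foot-off instant, %
#' @param angles named list (canonical angle names) of
#'   `list(mean = <numeric>, std = <numeric>)`; `NA` marks missing cells
#' @param demographics optional `list(age, height, weight)`
#' @return Object of class `subject_record`.
#' @export
subject_record <- function(subject_id, condition, foot_off_mean, foot_off_std,
                           angles, demographics = NULL) {
  structure(
    list(subject_id = subject_id, condition = condition,
         foot_off_mean = foot_off_mean, foot_off_std = foot_off_std,
         angles = angles, demographics = demographics),
    class = "subject_record"
  )
}

#' Gait cohort container
#'
#' An ordered list of [subject_record()]s with free-text provenance.
#'
#' @param subjects list of subject records
#' @param provenance free-text origin note (generator seed, source file, ...)
#' @return Object of class `gait_cohort`.
#' @export
gait_cohort <- function(subjects, provenance = "") {
  ids <- vapply(subjects, function(s) s$subject_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate subject_id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  structure(list(subjects = subjects, provenance = provenance),
            class = "gait_cohort")
}

#' @export
print.gait_cohort <- function(x, ...) {
  cat(sprintf("gait_cohort: %d subjects\n", length(x$subjects)))
  if (length(x$subjects) > 0L) {
    tab <- table(cohort_labels(x))
    for (nm in names(tab)) cat(sprintf("  %-55s %d\n", nm, tab[[nm]]))
  }
  if (nzchar(x$provenance)) cat("provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
summary.gait_cohort <- function(object, ...) {
  cat(sprintf("gait_cohort: %d subjects, missing fraction %.4f\n",
              length(object$subjects), missing_fraction(object)))
  print(table(cohort_labels(object)))
  invisible(object)
}

#' Condition labels of a cohort, in subject order
#' @param cohort a [gait_cohort()]
#' @return Character vector.
#' @export
cohort_labels <- function(cohort) {
  vapply(cohort$subjects, function(s) s$condition, character(1))
}

#' Subject ids of a cohort, in subject order
#' @param cohort a [gait_cohort()]
#' @return Character vector.
#' @export
cohort_ids <- function(cohort) {
  vapply(cohort$subjects, function(s) s$subject_id, character(1))
}

#' Subset a cohort by subject id
#' @param cohort a [gait_cohort()]
#' @param ids subject ids to keep, in the given order
#' @return A [gait_cohort()].
#' @export
subset_cohort <- function(cohort, ids) {
  all_ids <- cohort_ids(cohort)
  missing <- setdiff(ids, all_ids)
  if (length(missing) > 0L) {
    stop("unknown subject id(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  gait_cohort(cohort$subjects[match(ids, all_ids)], provenance = cohort$provenance)
}

#' Validate a cohort against the data-model invariants
#'
#' Checks, per subject: exactly the 12 canonical angles are present; series
#' have the canonical grid length of 101; std series are nonnegative where
#' observed; the foot-off instant lies strictly inside (0, 100). Violations
#' are returned as data, not raised.
#'
#' @param cohort a [gait_cohort()]
#' @param require_complete also flag missing (`NA`) cells
#' @return data.frame with columns `subject_id`, `field`, `reason`;
#'   zero rows when the cohort is valid.
#' @export
validate_cohort <- function(cohort, require_complete = FALSE) {
  v <- list()
  add <- function(id, field, reason) {
    v[[length(v) + 1L]] <<- data.frame(subject_id = id, field = field,
                                       reason = reason, stringsAsFactors = FALSE)
  }
  canon <- gait_angles()
  for (s in cohort$subjects) {
    got <- names(s$angles)
    absent <- setdiff(canon, got)
    extra <- setdiff(got, canon)
    for (a in absent) add(s$subject_id, a, "missing angle")
    for (a in extra) add(s$subject_id, a, "non-canonical angle name")
    if (!is.finite(s$foot_off_mean) || s$foot_off_mean <= 0 || s$foot_off_mean >= 100) {
      add(s$subject_id, "foot_off_mean", "foot-off out of range")
    }
    if (!is.finite(s$foot_off_std) || s$foot_off_std < 0) {
      add(s$subject_id, "foot_off_std", "negative std")
    }
    for (a in intersect(got, canon)) {
      for (kind in c("mean", "std")) {
        ser <- s$angles[[a]][[kind]]
        if (length(ser) != GRID_N) {
          add(s$subject_id, paste(a, kind, sep = "|"),
              sprintf("series length %d, expected %d", length(ser), GRID_N))
          next
        }
        if (any(is.infinite(ser))) {
          add(s$subject_id, paste(a, kind, sep = "|"), "non-finite value")
        }
        if (kind == "std" && any(ser < 0, na.rm = TRUE)) {
          add(s$subject_id, paste(a, kind, sep = "|"), "negative std")
        }
        if (require_complete && anyNA(ser)) {
          add(s$subject_id, paste(a, kind, sep = "|"), "missing value")
        }
      }
    }
  }
  if (length(v) == 0L) {
    return(data.frame(subject_id = character(), field = character(),
                      reason = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, v)
}

#' Write / read a cohort as a long CSV
#'
#' Single-file long format: one `series` row per (subject, angle, series
#' kind, grid index k, value) and one `meta` row per subject (condition,
#' foot-off mean/std, demographics). Values are stored at 6 decimals;
#' missing cells are written as empty fields and read back as `NA`, never
#' zero. Comment lines start with `#`; the footer carries a row-count
#' checksum so silently truncated files are rejected on read.
#'
#' @param cohort a [gait_cohort()]
#' @param path file path
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns a
#'   validated [gait_cohort()].
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "gait_cohort"))
  meta <- data.table::rbindlist(lapply(cohort$subjects, function(s) {
    d <- s$demographics %||% list(age = NA_real_, height = NA_real_, weight = NA_real_)
    data.table::data.table(
      section = "meta", subject_id = s$subject_id, condition = s$condition,
      foot_off_mean = round(s$foot_off_mean, 6), foot_off_std = round(s$foot_off_std, 6),
      age = round(d$age %||% NA_real_, 6), height = round(d$height %||% NA_real_, 6),
      weight = round(d$weight %||% NA_real_, 6),
      angle = NA_character_, kind = NA_character_, k = NA_integer_, value = NA_real_
    )
  }))
  series <- data.table::rbindlist(lapply(cohort$subjects, function(s) {
    data.table::rbindlist(lapply(names(s$angles), function(a) {
      data.table::rbindlist(lapply(c("mean", "std"), function(kind) {
        ser <- s$angles[[a]][[kind]]
        data.table::data.table(
          section = "series", subject_id = s$subject_id, condition = NA_character_,
          foot_off_mean = NA_real_, foot_off_std = NA_real_,
          age = NA_real_, height = NA_real_, weight = NA_real_,
          angle = a, kind = kind, k = seq_along(ser) - 1L,
          value = round(ser, 6)
        )
      }))
    }))
  }))
  tab <- rbind(meta, series)
  writeLines(c("# gaitpath cohort v1",
               paste0("# provenance: ", gsub("[\r\n]", " ", cohort$provenance))),
             path, useBytes = TRUE)
  data.table::fwrite(tab, path, na = "", append = TRUE, col.names = TRUE)
  cat(sprintf("# rows=%d\n", nrow(tab)), file = path, append = TRUE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  comments <- grep("^#", lines)
  prov <- sub("^# provenance: ?", "", grep("^# provenance:", lines, value = TRUE))
  footer <- grep("^# rows=", lines, value = TRUE)
  body <- if (length(comments)) lines[-comments] else lines
  tab <- data.table::fread(text = body, na.strings = "", sep = ",")
  req <- c("section", "subject_id", "condition", "foot_off_mean", "foot_off_std",
           "age", "height", "weight", "angle", "kind", "k", "value")
  absent <- setdiff(req, names(tab))
  if (length(absent) > 0L) {
    stop("cohort file missing required column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  if (length(footer) != 1L) {
    stop("cohort file has no row-count footer; refusing possibly truncated file",
         call. = FALSE)
  }
  expected <- as.integer(sub("^# rows=", "", footer))
  if (nrow(tab) != expected) {
    stop(sprintf("cohort file truncated: footer declares %d rows, found %d",
                 expected, nrow(tab)), call. = FALSE)
  }
  ser <- tab[tab$section == "series", ]
  meta <- tab[tab$section == "meta", ]
  bad_angle <- setdiff(unique(ser$angle), gait_angles())
  if (length(bad_angle) > 0L) {
    stop("non-canonical angle name(s): ", paste(bad_angle, collapse = ", "),
         call. = FALSE)
  }
  if (any(ser$k < 0L | ser$k > 100L)) {
    bad <- which(ser$k < 0L | ser$k > 100L)
    stop("grid index k outside 0..100 in series rows: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  key <- paste(ser$subject_id, ser$angle, ser$kind, ser$k)
  if (anyDuplicated(key)) {
    stop("duplicate (subject, angle, kind, k) rows: ",
         paste(utils::head(unique(key[duplicated(key)]), 5), collapse = "; "),
         call. = FALSE)
  }
  subjects <- lapply(seq_len(nrow(meta)), function(i) {
    id <- meta$subject_id[i]
    rows <- ser[ser$subject_id == id, ]
    got <- unique(rows$angle)
    absent <- setdiff(gait_angles(), got)
    if (length(absent) > 0L) {
      stop(sprintf("subject %s lacks angle(s): %s", id,
                   paste(absent, collapse = ", ")), call. = FALSE)
    }
    angles <- lapply(gait_angles(), function(a) {
      lapply(stats::setNames(c("mean", "std"), c("mean", "std")), function(kind) {
        r <- rows[rows$angle == a & rows$kind == kind, ]
        out <- rep(NA_real_, GRID_N)
        out[r$k + 1L] <- r$value
        out
      })
    })
    names(angles) <- gait_angles()
    demo <- list(age = meta$age[i], height = meta$height[i], weight = meta$weight[i])
    subject_record(id, meta$condition[i], meta$foot_off_mean[i],
                   meta$foot_off_std[i], angles, demo)
  })
  cohort <- gait_cohort(subjects, provenance = if (length(prov)) prov else "")
  viol <- validate_cohort(cohort)
  viol <- viol[viol$reason != "missing value", , drop = FALSE]
  if (nrow(viol) > 0L) {
    stop("cohort file fails validation:\n",
         paste(sprintf("  %s / %s: %s", viol$subject_id, viol$field, viol$reason),
               collapse = "\n"), call. = FALSE)
  }
  cohort
}

#' Write / read a feature table as a wide CSV
#'
#' Header is `subject_id`, the canonical 374 feature names, then
#' `condition`. Values are stored at 6 decimals; empty cells are missing.
#' On read the header is checked column-by-column against the canonical
#' enumeration and the first mismatch is reported.
#'
#' @param table a feature table (data.frame from [extract_cohort_features()])
#' @param path file path
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` the validated table.
#' @export
write_feature_table <- function(table, path) {
  canon <- c("subject_id", enumerate_feature_names(), "condition")
  absent <- setdiff(canon, names(table))
  if (length(absent) > 0L) {
    stop("feature table missing column(s), first: ", absent[1L], call. = FALSE)
  }
  out <- table[, canon]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], round, digits = 6)
  data.table::fwrite(out, path, na = "")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- as.data.frame(data.table::fread(path, na.strings = "", sep = ","),
                       check.names = FALSE)
  canon <- c("subject_id", enumerate_feature_names(), "condition")
  if (length(names(tab)) != length(canon)) {
    stop(sprintf("feature table has %d columns, expected %d",
                 length(names(tab)), length(canon)), call. = FALSE)
  }
  mismatch <- which(names(tab) != canon)
  if (length(mismatch) > 0L) {
    stop(sprintf("feature table header mismatch at column %d: got '%s', expected '%s'",
                 mismatch[1L], names(tab)[mismatch[1L]], canon[mismatch[1L]]),
         call. = FALSE)
  }
  tab
}
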