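#' Normative reference
#'
#' Per-angle 101-point reference series, computed by averaging the mean
#' series point-wise across all typically developed subjects in the cohort.
#' The reference is the baseline for the difference-from-normative series.
#'
#' @param cohort a [gait_cohort()] with missing values already imputed
#' @return Object of class `normative_reference`: a named list of numeric
#'   101-vectors, one per canonical angle.
#' @export
compute_normative <- function(cohort) {
  stopifnot(inherits(cohort, "gait_cohort"))
  typ <- Filter(function(s) s$condition == typical_label(), cohort$subjects)
  if (length(typ) == 0L) {
    stop("normative undefined: cohort has no '", typical_label(), "' subjects",
         call. = FALSE)
  }
  ref <- lapply(gait_angles(), function(a) {
    m <- vapply(typ, function(s) s$angles[[a]]$mean, numeric(GRID_N))
    if (anyNA(m)) stop("impute before computing the normative reference", call. = FALSE)
    rowMeans(m)
  })
  names(ref) <- gait_angles()
  structure(ref, class = "normative_reference")
}

#' First gradient of a gait series
#'
#' Discrete central difference `V[k] = (U[k+1] - U[k-1]) / 2` for
#' `k = 1..99`. The endpoints `k = 0, 100` have no central difference and
#' the gradient series is therefore defined on the 99 interior points only;
#' no one-sided padding is invented.
#'
#' @param series numeric vector of length 101, no missing values
#' @return Numeric vector of length 99 (grid indices 1..99).
#' @export
first_gradient <- function(series) {
  n <- length(series)
  if (n < 3L) stop("series too short for a central difference", call. = FALSE)
  if (anyNA(series)) stop("impute before derivation", call. = FALSE)
  (series[3:n] - series[1:(n - 2L)]) / 2
}

#' Difference from the normative reference
#'
#' Point-wise absolute deviation `DN[k] = |U[k] - U_norm[k]|`,
#' nonnegative by construction.
#'
#' @param series subject mean series (length 101, no missing values)
#' @param u_norm normative series for the same angle (length 101)
#' @return Numeric vector of length 101.
#' @export
difference_from_normative <- function(series, u_norm) {
  if (length(series) != length(u_norm)) {
    stop(sprintf("length mismatch: series %d vs normative %d",
                 length(series), length(u_norm)), call. = FALSE)
  }
  if (anyNA(series) || anyNA(u_norm)) stop("impute before derivation", call. = FALSE)
  abs(series - u_norm)
}

#' Derived series set for one subject and angle
#'
#' Bundles the four series feature extraction works on: the subject's mean
#' and std series, the first gradient of the mean (interior grid 1..99) and
#' the difference from normative (full grid).
#'
#' @param subject a [subject_record()] (imputed)
#' @param normative a [compute_normative()] reference
#' @return Named list (per angle) of lists with elements `mean`, `std`,
#'   `first_gradient`, `diff_norm`.
#' @export
derive_series <- function(subject, normative) {
  out <- lapply(gait_angles(), function(a) {
    u <- subject$angles[[a]]$mean
    list(
      mean = u,
      std = subject$angles[[a]]$std,
      first_gradient = first_gradient(u),
      diff_norm = difference_from_normative(u, normative[[a]])
    )
  })
  names(out) <- gait_angles()
  out
}

#' Write / read a normative reference as CSV
#'
#' Wide CSV: column `k` (0..100) plus one column per canonical angle.
#'
#' @param normative a `normative_reference`
#' @param path file path
#' @return `write_normative` returns `path` invisibly; `read_normative` the
#'   reference.
#' @export
write_normative <- function(normative, path) {
  tab <- data.frame(k = gait_grid(), check.names = FALSE)
  for (a in gait_angles()) tab[[a]] <- round(normative[[a]], 6)
  data.table::fwrite(tab, path)
  invisible(path)
}

#' @rdname write_normative
#' @export
read_normative <- function(path) {
  tab <- as.data.frame(data.table::fread(path, sep = ","), check.names = FALSE)
  absent <- setdiff(gait_angles(), names(tab))
  if (length(absent) > 0L) {
    stop("normative file missing angle(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(tab) != GRID_N) {
    stop(sprintf("normative file has %d rows, expected %d", nrow(tab), GRID_N),
         call. = FALSE)
  }
  ref <- lapply(gait_angles(), function(a) tab[[a]])
  names(ref) <- gait_angles()
  structure(ref, class = "normative_reference")
}
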