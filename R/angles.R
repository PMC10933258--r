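#' Canonical functional-angle vocabulary
#'
#' The twelve functional foot and ankle angles of the Heidelberg Foot
#' Measurement Method, in the canonical order used throughout the package.
#' Every module resolves angle names through this vector; any other spelling
#' is rejected at validation time.
#'
#' @return Character vector of the 12 canonical angle names.
#' @export
#' @examples
#' gait_angles()
gait_angles <- function() {
  c(
    "Tibiotalar flexion",
    "Medial arch inclination",
    "Medial arch angle",
    "Lateral arch angle",
    "Subtalar inversion",
    "Forefoot/ankle supination",
    "Forefoot/midfoot supination",
    "Forefoot/hindfoot abduction",
    "Forefoot/ankle abduction",
    "Inter MT I-V angle",
    "Hallux adduction",
    "Hallux flexion"
  )
}

#' Condition labels
#'
#' The seven foot-condition class labels: six pathologies plus the
#' typically developed control group.
#'
#' @return Character vector of 7 labels; the control label is last.
#' @export
gait_conditions <- function() {
  c(
    "Tibiotalar osteoarthritis + partial ankle replacement",
    "Planovalgus",
    "Consolidated calcaneal fracture",
    "Hallux rigidus",
    "Clubfoot",
    "Cavovarus",
    "Typical feet"
  )
}

#' @rdname gait_conditions
#' @export
typical_label <- function() "Typical feet"

# internal: assert angle names are canonical
check_angles <- function(angles) {
  bad <- setdiff(angles, gait_angles())
  if (length(bad) > 0L) {
    stop("unknown angle name(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(angles)
}

# grid length of a cycle-normalized series (0..100% in 1% steps)
GRID_N <- 101L

#' Gait-cycle grid
#'
#' The percentage-of-gait-cycle grid on which all series live: 101 evenly
#' spaced points, indices `k = 0..100`, units % gait cycle.
#'
#' @return Integer vector `0:100`.
#' @export
gait_grid <- function() 0:100
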