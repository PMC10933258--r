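#' Configuration for a synthetic gait cohort
#'
#' Defaults replicate the structure of the reference clinical cohort:
#' 248 patients across six foot conditions plus 100 typically developed
#' controls (348 subjects), 101-point cycle-normalized series, foot-off
#' near 60% of the gait cycle.
#'
#' @param class_counts named integer vector, condition label -> subject count
#' @param n_points grid length (101 for the canonical 0--100% grid)
#' @param foot_off_mean_pct population mean foot-off instant, % gait cycle
#' @param foot_off_sd_pct between-subject sd of the foot-off instant, %
#' @param noise_sd_deg sd of the per-subject additive offset jitter, degrees
#' @param missing_rate fraction of grid cells replaced by missing values
#' @param seed integer seed; equal (config, seed) gives bit-identical cohorts
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(class_counts = default_class_counts(),
                          n_points = 101L,
                          foot_off_mean_pct = 60,
                          foot_off_sd_pct = 2,
                          noise_sd_deg = 1.5,
                          missing_rate = 0.02,
                          seed = 1L) {
  if (is.null(names(class_counts)) || any(!nzchar(names(class_counts)))) {
    stop("class_counts must be a named vector of condition labels", call. = FALSE)
  }
  if (any(class_counts < 0)) stop("all class counts must be >= 0", call. = FALSE)
  if (n_points < 3L) stop("n_points must be >= 3", call. = FALSE)
  if (foot_off_mean_pct <= 0 || foot_off_mean_pct >= 100) {
    stop("foot_off_mean_pct must lie strictly inside (0, 100)", call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  }
  structure(
    list(
      class_counts = class_counts, n_points = as.integer(n_points),
      foot_off_mean_pct = foot_off_mean_pct, foot_off_sd_pct = foot_off_sd_pct,
      noise_sd_deg = noise_sd_deg, missing_rate = missing_rate,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' @rdname cohort_config
#' @export
default_class_counts <- function() {
  stats::setNames(
    c(58L, 64L, 20L, 40L, 41L, 25L, 100L),
    gait_conditions()
  )
}

# Demographics of the reference cohort per class: age (yr), height (cm),
# weight (kg), mean and sd. Carried as metadata only, never used as features.
demographic_table <- function() {
  d <- data.frame(
    condition = gait_conditions(),
    age_mean = c(57.9, 31.3, 52.5, 58.6, 11.8, 19.5, 24.0),
    age_sd = c(11.7, 15.6, 10.4, 8.2, 9.3, 14.9, 15.2),
    height_mean = c(170.5, 171.9, 178.0, 168.2, 140.1, 161.0, 159.8),
    height_sd = c(8.6, 12.4, 8.2, 9.6, 28.2, 18.9, 23.7),
    weight_mean = c(82.6, 71.7, 86.6, 74.8, 41.5, 59.7, 55.6),
    weight_sd = c(17.7, 20.1, 11.7, 13.3, 21.8, 23.1, 23.9)
  )
  d
}

# Per-angle 3-harmonic base waveform templates: value(t) = b0 +
# a1*sin(2*pi*t + p1) + a2*sin(4*pi*t + p2), t in [0, 1]. Package constants;
# amplitudes vary across angles so that min-max scaling is exercised.
waveform_templates <- function() {
  data.frame(
    angle = gait_angles(),
    b0 = c(5, 10, 120, 150, 2, 8, 4, -5, -8, 10, 6, 15),
    a1 = c(12, 4, 8, 6, 5, 6, 3, 4, 5, 3, 4, 14),
    p1 = c(0.3, 1.1, 2.0, 0.7, 1.6, 0.2, 2.4, 3.0, 0.9, 1.3, 2.7, 0.5),
    a2 = c(4, 1.5, 3, 2, 2, 2.5, 1, 1.5, 2, 1, 1.5, 5),
    p2 = c(1.2, 0.4, 2.9, 1.8, 0.6, 2.2, 1.0, 0.2, 2.6, 1.9, 0.8, 1.5)
  )
}

#' Planted kinematic effect specification
#'
#' Describes, for one condition, the perturbations applied on top of the
#' shared base waveforms: each effect targets one angle's mean or std series
#' over a phase window with an offset (degrees), an amplitude scaling about
#' the window mean (unitless factor), or a timing shift (% cycle,
#' circular).
#'
#' @param condition condition label
#' @param effects data.frame with columns `angle`, `series` (mean/std),
#'   `phase` (stance/swing/full), `effect` (offset/amplitude_scale/
#'   timing_shift), `magnitude`
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(condition, effects) {
  stopifnot(is.data.frame(effects))
  req <- c("angle", "series", "phase", "effect", "magnitude")
  if (!all(req %in% names(effects))) {
    stop("effects must have columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  check_angles(effects$angle)
  if (!all(effects$series %in% c("mean", "std"))) stop("bad series kind", call. = FALSE)
  if (!all(effects$phase %in% c("stance", "swing", "full"))) stop("bad phase", call. = FALSE)
  if (!all(effects$effect %in% c("offset", "amplitude_scale", "timing_shift"))) {
    stop("bad effect kind", call. = FALSE)
  }
  if (any(!is.finite(effects$magnitude))) stop("magnitudes must be finite", call. = FALSE)
  structure(list(condition = condition, effects = effects), class = "effect_spec")
}

one_effect <- function(angle, series, phase, effect, magnitude) {
  data.frame(angle = angle, series = series, phase = phase,
             effect = effect, magnitude = magnitude, stringsAsFactors = FALSE)
}

#' Default registry of per-condition planted effects
#'
#' One [effect_spec()] per pathological condition; typically developed
#' controls are unperturbed. The directions follow clinical expectation --
#' planovalgus lowers and cavovarus raises the medial arch, clubfoot turns
#' the foot inward (abduction/supination offsets), hallux rigidus restricts
#' hallux and tibiotalar motion, a consolidated calcaneal fracture shifts
#' subtalar inversion and inflates stride variability, and ankle
#' osteoarthritis with partial replacement damps tibiotalar motion with a
#' moderate medial-arch shift. Magnitudes are calibrated for signal
#' recoverability against the generator's jitter, not clinical realism.
#'
#' @param magnitude_scale multiply every offset magnitude and shrink every
#'   amplitude factor toward 1 by this factor; `0` yields a null registry in
#'   which patient classes are distributionally identical to controls
#' @return Named list of `effect_spec`, keyed by the 6 pathological labels.
#' @export
condition_effect_registry <- function(magnitude_scale = 1) {
  cond <- gait_conditions()
  specs <- list(
    effect_spec(cond[1L], rbind(  # osteoarthritis + partial ankle replacement
      one_effect("Tibiotalar flexion", "mean", "full", "amplitude_scale", 0.55),
      one_effect("Medial arch angle", "mean", "full", "offset", 4)
    )),
    effect_spec(cond[2L],          # planovalgus: collapsed medial arch
      one_effect("Medial arch angle", "mean", "full", "offset", -8)
    ),
    effect_spec(cond[3L], rbind(  # consolidated calcaneal fracture
      one_effect("Subtalar inversion", "mean", "full", "offset", 7),
      one_effect("Subtalar inversion", "std", "full", "amplitude_scale", 2.5)
    )),
    effect_spec(cond[4L], rbind(  # hallux rigidus: restricted motion
      one_effect("Hallux flexion", "mean", "full", "amplitude_scale", 0.45),
      one_effect("Tibiotalar flexion", "mean", "full", "amplitude_scale", 0.7)
    )),
    effect_spec(cond[5L], rbind(  # clubfoot: inward-turned foot
      one_effect("Forefoot/ankle abduction", "mean", "full", "offset", -10),
      one_effect("Forefoot/ankle supination", "mean", "full", "offset", 8)
    )),
    effect_spec(cond[6L],          # cavovarus: exaggerated medial arch
      one_effect("Medial arch angle", "mean", "full", "offset", 8)
    )
  )
  names(specs) <- cond[1:6]
  if (magnitude_scale != 1) {
    specs <- lapply(specs, function(s) {
      e <- s$effects
      off <- e$effect %in% c("offset", "timing_shift")
      e$magnitude[off] <- e$magnitude[off] * magnitude_scale
      e$magnitude[!off] <- 1 + (e$magnitude[!off] - 1) * magnitude_scale
      effect_spec(s$condition, e)
    })
  }
  specs
}

# apply one effect_spec to a subject's angle series (in place), using the
# subject's own foot-off to resolve phase windows
apply_effects <- function(angles, spec, foot_off, n_points) {
  if (is.null(spec)) return(angles)
  r <- round_half_up(foot_off * (n_points - 1L) / 100)
  for (i in seq_len(nrow(spec$effects))) {
    e <- spec$effects[i, ]
    idx <- switch(e$phase,
      stance = 1:(r + 1L),
      swing = (r + 1L):n_points,
      full = seq_len(n_points)
    )
    s <- angles[[e$angle]][[e$series]]
    if (e$effect == "offset") {
      s[idx] <- s[idx] + e$magnitude
    } else if (e$effect == "amplitude_scale") {
      m <- mean(s[idx])
      s[idx] <- m + (s[idx] - m) * e$magnitude
    } else { # timing_shift: circular shift of the full series, % cycle
      sh <- round_half_up(e$magnitude * (n_points - 1L) / 100) %% n_points
      if (sh != 0) s <- c(s[(n_points - sh + 1L):n_points], s[1:(n_points - sh)])
    }
    if (e$series == "std") s <- pmax(s, 0)
    angles[[e$angle]][[e$series]] <- s
  }
  angles
}

#' Generate a synthetic gait cohort
#'
#' Every subject receives, per angle, a smooth 3-harmonic base mean waveform
#' with subject-level jitter (additive offset sd `noise_sd_deg`, amplitude
#' factor uniform in ±10%, phase shift uniform in ±2% of cycle) and a
#' nonnegative stride-variability (std) envelope `|N(1.5, 0.5)|` degrees.
#' Subjects of a pathological condition additionally carry that condition's
#' planted effects from `registry`. Demographics are drawn from the
#' per-class reference means and sds and carried as metadata only.
#'
#' @param config a [cohort_config()]
#' @param registry named list of [effect_spec()] (default
#'   [condition_effect_registry()]); conditions absent from the registry are
#'   unperturbed
#' @return A [gait_cohort()] of `sum(class_counts)` subjects.
#' @export
generate_cohort <- function(config = cohort_config(),
                            registry = condition_effect_registry()) {
  stopifnot(inherits(config, "cohort_config"))
  known <- gait_conditions()
  bad <- setdiff(names(config$class_counts), known)
  if (length(bad) > 0L) {
    stop("unknown condition label(s) in class_counts: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  tmpl <- waveform_templates()
  demo <- demographic_table()
  n_points <- config$n_points
  tt <- seq(0, 1, length.out = n_points)
  subjects <- list()
  idx <- 0L
  with_seed(config$seed, {
    for (cond in names(config$class_counts)) {
      n_c <- config$class_counts[[cond]]
      if (n_c == 0L) next
      spec <- registry[[cond]]
      dd <- demo[demo$condition == cond, ]
      for (s in seq_len(n_c)) {
        idx <- idx + 1L
        foot_off <- min(max(stats::rnorm(1, config$foot_off_mean_pct,
                                         config$foot_off_sd_pct), 1), 99)
        angles <- vector("list", nrow(tmpl))
        names(angles) <- tmpl$angle
        for (a in seq_len(nrow(tmpl))) {
          off <- stats::rnorm(1, 0, config$noise_sd_deg)
          amp <- stats::runif(1, 0.9, 1.1)
          ph <- stats::runif(1, -0.02, 0.02)
          u <- tmpl$b0[a] + off +
            amp * tmpl$a1[a] * sin(2 * pi * (tt + ph) + tmpl$p1[a]) +
            amp * tmpl$a2[a] * sin(4 * pi * (tt + ph) + tmpl$p2[a])
          sd_env <- abs(stats::rnorm(n_points, 1.5, 0.5))
          angles[[a]] <- list(mean = u, std = sd_env)
        }
        angles <- apply_effects(angles, spec, foot_off, n_points)
        demo_row <- if (nrow(dd) == 1L) {
          list(age = stats::rnorm(1, dd$age_mean, dd$age_sd),
               height = stats::rnorm(1, dd$height_mean, dd$height_sd),
               weight = stats::rnorm(1, dd$weight_mean, dd$weight_sd))
        } else {
          list(age = NA_real_, height = NA_real_, weight = NA_real_)
        }
        subjects[[idx]] <- subject_record(
          subject_id = sprintf("S%04d", idx),
          condition = cond,
          foot_off_mean = foot_off,
          foot_off_std = abs(stats::rnorm(1, 1.5, 0.5)),
          angles = angles,
          demographics = demo_row
        )
      }
    }
  })
  cohort <- gait_cohort(subjects,
                        provenance = sprintf("synthetic; seed=%d", config$seed))
  if (config$missing_rate > 0) {
    cohort <- inject_missingness(cohort, config$missing_rate,
                                 seed = config$seed + 104729L)
  }
  cohort
}

#' Inject missing values into a cohort
#'
#' Replaces approximately `rate` of all grid cells -- uniformly over
#' (subject, angle, series kind, grid index) -- with `NA`. Labels, foot-off
#' values and demographics are untouched. Reproducible by seed.
#'
#' @param cohort a [gait_cohort()]
#' @param rate fraction in `[0, 1)`
#' @param seed integer seed
#' @return The cohort with missing cells.
#' @export
inject_missingness <- function(cohort, rate, seed = 1L) {
  stopifnot(inherits(cohort, "gait_cohort"))
  if (rate < 0 || rate >= 1) stop("rate must lie in [0, 1)", call. = FALSE)
  if (rate == 0) return(cohort)
  with_seed(as.integer(seed), {
    for (i in seq_along(cohort$subjects)) {
      for (a in names(cohort$subjects[[i]]$angles)) {
        for (kind in c("mean", "std")) {
          s <- cohort$subjects[[i]]$angles[[a]][[kind]]
          hit <- stats::runif(length(s)) < rate
          s[hit] <- NA_real_
          cohort$subjects[[i]]$angles[[a]][[kind]] <- s
        }
      }
    }
  })
  cohort
}

#' Fraction of missing grid cells in a cohort
#' @param cohort a [gait_cohort()]
#' @return Scalar fraction in `[0, 1]`.
#' @export
missing_fraction <- function(cohort) {
  tot <- 0L; miss <- 0L
  for (s in cohort$subjects) {
    for (a in s$angles) {
      tot <- tot + length(a$mean) + length(a$std)
      miss <- miss + sum(is.na(a$mean)) + sum(is.na(a$std))
    }
  }
  if (tot == 0L) return(0)
  miss / tot
}
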