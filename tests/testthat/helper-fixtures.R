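# Shared fixtures, built in code and memoized per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, value) {
  if (!exists(key, envir = .fixture_env)) assign(key, value, envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# small balanced cohort config: every pathological class plus controls
small_config <- function(n_per_class = 8L, n_typical = 12L, seed = 11L,
                         missing_rate = 0.02) {
  counts <- stats::setNames(
    c(rep(n_per_class, 6L), n_typical), gait_conditions()
  )
  cohort_config(class_counts = counts, seed = seed, missing_rate = missing_rate)
}

# a complete (no missing cells) small cohort, shared across tests
tiny_cohort <- function() {
  memo("tiny_cohort", {
    cfg <- small_config(missing_rate = 0)
    generate_cohort(cfg)
  })
}

# its feature table (unscaled, original units)
tiny_features <- function() {
  memo("tiny_features", {
    co <- tiny_cohort()
    nv <- compute_normative(co)
    extract_cohort_features(co, nv)
  })
}

# hand-built subject whose every series is a supplied function of k
make_subject <- function(id = "T1", condition = "Typical feet",
                         foot_off = 60, mean_fn = function(k) rep(0, length(k)),
                         std_fn = function(k) rep(1, length(k))) {
  k <- 0:100
  angles <- lapply(gait_angles(), function(a) {
    list(mean = mean_fn(k), std = std_fn(k))
  })
  names(angles) <- gait_angles()
  subject_record(id, condition, foot_off, 1.2, angles)
}

flat_normative <- function(value = 0) {
  ref <- lapply(gait_angles(), function(a) rep(value, 101))
  names(ref) <- gait_angles()
  structure(ref, class = "normative_reference")
}
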