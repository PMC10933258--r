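test_that("phase segmentation rounds half up and shares the boundary index", {
  w <- segment_phases(60)
  expect_equal(w$stance, 0:60)
  expect_equal(w$swing, 60:100)
  expect_equal(segment_phases(59.5)$r, 60L)
  expect_equal(segment_phases(60.4)$r, 60L)
  expect_error(segment_phases(100), "strictly inside")
  expect_error(segment_phases(0), "strictly inside")
  expect_error(segment_phases(0.3), "degenerate")
})

test_that("constant series yield degenerate extrema at the window start", {
  s <- make_subject("C", mean_fn = function(k) rep(7, length(k)),
                    std_fn = function(k) rep(2, length(k)))
  fv <- extract_features(s, derive_series(s, flat_normative()), segment_phases(60))
  expect_equal(fv[["Tibiotalar flexion|mean|stance|max"]], 7)
  expect_equal(fv[["Tibiotalar flexion|mean|stance|min"]], 7)
  expect_equal(fv[["Tibiotalar flexion|mean|stance|timing_max"]], 0)
  expect_equal(fv[["Tibiotalar flexion|mean|swing|timing_min"]], 60)
  expect_equal(fv[["Tibiotalar flexion|mean|full|range_of_motion"]], 0)
  # the gradient window starts at the interior grid
  expect_equal(fv[["Tibiotalar flexion|first_gradient|stance|timing_max"]], 1)
  expect_equal(fv[["Tibiotalar flexion|diff_norm|stance|avg_diff_norm"]], 7)
})

test_that("the identity ramp puts extrema at the window edges", {
  s <- make_subject("R", mean_fn = function(k) as.numeric(k))
  fv <- extract_features(s, derive_series(s, flat_normative()), segment_phases(60))
  expect_equal(fv[["Hallux flexion|mean|stance|max"]], 60)
  expect_equal(fv[["Hallux flexion|mean|stance|timing_max"]], 60)
  expect_equal(fv[["Hallux flexion|mean|swing|max"]], 100)
  expect_equal(fv[["Hallux flexion|mean|swing|timing_max"]], 100)
  expect_equal(fv[["Hallux flexion|mean|stance|min"]], 0)
  expect_equal(fv[["Hallux flexion|mean|full|range_of_motion"]], 100)
  expect_equal(fv[["Foot_off|mean|full|value"]], 60)
})

test_that("a full feature vector matches an independent brute-force recomputation", {
  co <- tiny_cohort()
  nv <- compute_normative(co)
  s <- co$subjects[[5]]
  windows <- segment_phases(s$foot_off_mean)
  fv <- extract_features(s, derive_series(s, nv), windows)
  r <- windows$r
  # naive double-loop oracle over every (angle, series, phase, statistic)
  for (a in gait_angles()) {
    u <- s$angles[[a]]$mean
    series <- list(
      mean = list(vals = u, grid = 0:100),
      std = list(vals = s$angles[[a]]$std, grid = 0:100),
      first_gradient = list(
        vals = sapply(2:100, function(i) (u[i + 1] - u[i - 1]) / 2),
        grid = 1:99
      ),
      diff_norm = list(vals = abs(u - nv[[a]]), grid = 0:100)
    )
    for (ser in names(series)) {
      for (ph in c("stance", "swing")) {
        win <- if (ph == "stance") 0:r else r:100
        keep <- series[[ser]]$grid %in% win
        v <- series[[ser]]$vals[keep]; g <- series[[ser]]$grid[keep]
        checks <- list(max = max(v), timing_max = g[which.max(v)],
                       min = min(v), timing_min = g[which.min(v)])
        stats_here <- if (ser == "std") c("max", "timing_max") else names(checks)
        for (st in stats_here) {
          expect_lt(abs(fv[[feature_name(a, ser, ph, st)]] - checks[[st]]), 1e-9)
        }
        if (ser == "diff_norm") {
          expect_lt(abs(fv[[feature_name(a, ser, ph, "avg_diff_norm")]] - mean(v)), 1e-9)
        }
      }
    }
    expect_lt(abs(fv[[feature_name(a, "mean", "full", "range_of_motion")]] -
                    (max(u) - min(u))), 1e-9)
  }
})

test_that("extrema, timings and range of motion satisfy the window invariants", {
  co <- tiny_cohort()
  nv <- compute_normative(co)
  for (s in co$subjects[seq(1, 60, by = 7)]) {
    w <- segment_phases(s$foot_off_mean)
    fv <- extract_features(s, derive_series(s, nv), w)
    for (a in gait_angles()[c(1, 5, 12)]) {
      for (ph in c("stance", "swing")) {
        expect_gte(fv[[feature_name(a, "mean", ph, "max")]],
                   fv[[feature_name(a, "mean", ph, "min")]])
        tmax <- fv[[feature_name(a, "mean", ph, "timing_max")]]
        expect_true(tmax >= min(w[[ph]]) && tmax <= max(w[[ph]]))
        tg <- fv[[feature_name(a, "first_gradient", ph, "timing_min")]]
        expect_true(tg >= max(1, min(w[[ph]])) && tg <= min(99, max(w[[ph]])))
      }
      expect_gte(fv[[feature_name(a, "mean", "full", "range_of_motion")]], 0)
    }
  }
})

test_that("shifting a series by a constant shifts extrema but not timings", {
  co <- tiny_cohort()
  nv <- compute_normative(co)
  s <- co$subjects[[3]]
  s2 <- s
  for (a in gait_angles()) s2$angles[[a]]$mean <- s2$angles[[a]]$mean + 11
  w <- segment_phases(s$foot_off_mean)
  f1 <- extract_features(s, derive_series(s, nv), w)
  f2 <- extract_features(s2, derive_series(s2, nv), w)
  a <- "Lateral arch angle"
  expect_equal(f2[[feature_name(a, "mean", "stance", "max")]],
               f1[[feature_name(a, "mean", "stance", "max")]] + 11)
  expect_equal(f2[[feature_name(a, "mean", "swing", "timing_min")]],
               f1[[feature_name(a, "mean", "swing", "timing_min")]])
  expect_equal(f2[[feature_name(a, "mean", "full", "range_of_motion")]],
               f1[[feature_name(a, "mean", "full", "range_of_motion")]])
})

test_that("cohort-level extraction is shaped, ordered, and subject-independent", {
  co <- tiny_cohort()
  nv <- compute_normative(co)
  ft <- tiny_features()
  expect_equal(nrow(ft), length(co$subjects))
  expect_identical(names(ft), c("subject_id", enumerate_feature_names(), "condition"))

  empty <- gait_cohort(list())
  ft0 <- extract_cohort_features(empty, nv)
  expect_equal(nrow(ft0), 0L)
  expect_identical(names(ft0), c("subject_id", enumerate_feature_names(), "condition"))

  perm <- gait_cohort(rev(co$subjects), provenance = co$provenance)
  ftp <- extract_cohort_features(perm, nv)
  reord <- ftp[match(ft$subject_id, ftp$subject_id), ]
  rownames(reord) <- NULL
  expect_equal(reord, ft)
})
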