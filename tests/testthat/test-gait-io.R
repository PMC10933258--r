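cohorts_equal <- function(a, b, tol = 1e-6) {
  expect_identical(cohort_ids(a), cohort_ids(b))
  expect_identical(cohort_labels(a), cohort_labels(b))
  for (i in seq_along(a$subjects)) {
    sa <- a$subjects[[i]]; sb <- b$subjects[[i]]
    expect_equal(sa$foot_off_mean, sb$foot_off_mean, tolerance = tol)
    for (ang in gait_angles()) {
      expect_equal(sa$angles[[ang]]$mean, sb$angles[[ang]]$mean, tolerance = tol)
      expect_equal(sa$angles[[ang]]$std, sb$angles[[ang]]$std, tolerance = tol)
    }
  }
}

test_that("cohort CSV round-trips at stored precision, including missing cells", {
  co <- inject_missingness(tiny_cohort(), 0.03, seed = 4L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  cohorts_equal(co, back)
  # missing cells survive as NA, never zero
  expect_equal(missing_fraction(back), missing_fraction(co))
})

test_that("readers reject malformed and truncated cohort files", {
  co <- generate_cohort(small_config(n_per_class = 1L, n_typical = 2L,
                                     missing_rate = 0))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)

  # drop one angle entirely for one subject
  lines <- readLines(path)
  id <- cohort_ids(co)[1L]
  drop <- grepl(paste0("^series,", id, ",.*Hallux flexion"), lines)
  trunc <- lines[!drop]
  n_body <- sum(!grepl("^#", trunc)) - 1L  # minus header
  trunc[grepl("^# rows=", trunc)] <- sprintf("# rows=%d", n_body)
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(trunc, p2)
  expect_error(read_cohort(p2), "Hallux flexion")

  # silently truncated file (footer checksum mismatch)
  p3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(lines[-c(length(lines) - 5L)], p3)
  expect_error(read_cohort(p3), "truncated")

  # no footer at all
  p4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(lines[!grepl("^# rows=", lines)], p4)
  expect_error(read_cohort(p4), "footer")
})

test_that("an empty value cell is read as the missing sentinel, not zero", {
  co <- generate_cohort(small_config(n_per_class = 1L, n_typical = 1L,
                                     missing_rate = 0))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  lines <- readLines(path)
  i <- grep("^series,.*,mean,5,", lines)[1L]
  lines[i] <- sub(",[-0-9.]+$", ",", lines[i])
  writeLines(lines, path)
  back <- read_cohort(path)
  hit <- vapply(back$subjects, function(s) {
    any(vapply(s$angles, function(a) is.na(a$mean[6L]), logical(1)))
  }, logical(1))
  expect_true(any(hit))
  vals <- unlist(lapply(back$subjects, function(s) {
    vapply(s$angles, function(a) a$mean[6L], numeric(1))
  }))
  expect_false(any(vals == 0 & !is.na(vals) &
                     abs(vals) < .Machine$double.eps))
})

test_that("validate_cohort reports violations as data", {
  co <- tiny_cohort()
  expect_equal(nrow(validate_cohort(co)), 0L)

  bad <- co
  bad$subjects[[1]]$angles[["Subtalar inversion"]]$std[10] <- -1
  v <- validate_cohort(bad)
  expect_equal(nrow(v), 1L)
  expect_match(v$reason, "negative std")
  expect_equal(v$subject_id, co$subjects[[1]]$subject_id)

  bad2 <- co
  bad2$subjects[[2]]$foot_off_mean <- 0
  v2 <- validate_cohort(bad2)
  expect_match(v2$reason, "foot-off out of range")

  bad3 <- co
  bad3$subjects[[3]]$angles[["Hallux flexion"]] <- NULL
  expect_true(any(validate_cohort(bad3)$reason == "missing angle"))
})

test_that("feature tables round-trip and reject header mismatches", {
  ft <- tiny_features()[1:3, ]
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(ft, path)
  back <- read_feature_table(path)
  expect_identical(names(back), c("subject_id", enumerate_feature_names(), "condition"))
  num <- enumerate_feature_names()
  expect_equal(as.matrix(back[, num]), as.matrix(ft[, num]), tolerance = 1e-6,
               ignore_attr = TRUE)

  # drop one feature column -> 373 features, named mismatch
  lines <- readLines(path)
  hdr <- strsplit(lines[1L], ",")[[1]]
  expect_error({
    short <- lapply(strsplit(lines, ","), function(x) x[-10L])
    p2 <- withr::local_tempfile(fileext = ".csv")
    writeLines(vapply(short, paste, character(1), collapse = ","), p2)
    read_feature_table(p2)
  }, "columns|mismatch")

  # missing cells are allowed and flagged to the imputation stage
  ft2 <- ft
  ft2[[enumerate_feature_names()[5]]][2] <- NA
  write_feature_table(ft2, path)
  back2 <- read_feature_table(path)
  expect_true(is.na(back2[[enumerate_feature_names()[5]]][2]))
})

test_that("duplicate subject ids are rejected at construction", {
  co <- tiny_cohort()
  subj <- co$subjects[c(1, 1)]
  expect_error(gait_cohort(subj), "duplicate subject_id")
})
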