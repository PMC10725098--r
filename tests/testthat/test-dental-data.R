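test_that("CAL thresholding uses a closed threshold and rejects negatives", {
  expect_equal(threshold_cal(c(3.0, 2.9, 0.0), 3.0), c(1L, 0L, 0L))
  expect_equal(threshold_cal(c(NA, 6), 3), c(NA_integer_, 1L))
  expect_error(threshold_cal(-0.1, 3), "nonnegative")
  expect_error(threshold_cal(1, -3))
})

test_that("cohort construction validates the tooth universe and site counts", {
  full <- make_cohort(list(c(2:15, 18:31)), list(rep(0L, 168)))
  expect_equal(periomi:::n_sites(full), 168L)
  expect_error(make_cohort(list(c(1, 2)), list(rep(0L, 12))),
               "third molars")
  expect_error(make_cohort(list(c(2, 3)), list(rep(0L, 11))),
               "expected 12")
  # 10 teeth -> n_i = 60
  ten <- make_cohort(list(2:11), list(rep(0L, 60)))
  expect_equal(periomi:::n_sites(ten), 60L)
})

test_that("long-format read/write round trip is exact", {
  co <- random_complete_cohort(5, seed = 3)
  # sprinkle both kinds of missingness
  co$status[[2]][c(1, 5)] <- NA_integer_
  co$miss[[2]][c(1, 5)] <- c(periomi:::MISS_TECHNICAL,
                             periomi:::MISS_NONSELECTED)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_identical(back$status, co$status)
  expect_identical(back$miss, co$miss)
  expect_identical(back$teeth, co$teeth)
  expect_equal(back$subjects$weight, co$subjects$weight)
})

test_that("long-format reader rejects malformed rows by position", {
  co <- make_cohort(list(c(2, 3)), list(rep(0L, 12)))
  df <- as.data.frame(co)
  bad <- df; bad$tooth[3] <- 16L
  expect_error(cohort_from_long(bad), "unknown tooth.*3")
  bad <- df; bad$site[4] <- "mesial"
  expect_error(cohort_from_long(bad), "unknown site.*4")
  expect_error(cohort_from_long(rbind(df, df[1, ])), "duplicate")
  bad <- df[-1, ]  # incomplete tooth
  expect_error(cohort_from_long(bad), "incomplete site rows")
})

test_that("wide-format mapping reader thresholds CAL and flags technical", {
  # one subject, 2 teeth, wide table with per-tooth-site CAL columns
  codes <- c("DB", "B", "MB", "ML", "L", "DL")
  cols <- as.vector(outer(codes, c(2, 3), function(s, t)
    sprintf("CAL_%02d_%s", t, s)))
  row <- as.list(c(3.1, 0, 2.9, 5, NA, 3,   # tooth 2
                   0, 0, 0, 0, 0, 0))       # tooth 3
  names(row) <- cols
  df <- data.frame(SEQN = "A1", RIDAGEYR = 64, row, check.names = FALSE)
  # all other teeth absent: columns must exist, all NA
  for (t in setdiff(c(2:15, 18:31), c(2, 3)))
    for (s in codes) df[[sprintf("CAL_%02d_%s", t, s)]] <- NA_real_
  mapping <- list(subject_id = "SEQN", age = "RIDAGEYR",
                  cal_template = "CAL_{tooth}_{code}")
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  co <- read_cohort(path, mapping = mapping)
  expect_equal(co$teeth[[1]], c(2L, 3L))
  expect_equal(co$subjects$age_group, "60-69")
  # tooth 2, canonical order DB B MB ML L DL: 3.1,0,2.9,5,NA,3 -> 1,0,0,1,NA,1
  expect_equal(co$status[[1]][1:6], c(1L, 0L, 0L, 1L, NA, 1L))
  expect_equal(co$miss[[1]][5], periomi:::MISS_TECHNICAL)
  expect_equal(co$status[[1]][7:12], rep(0L, 6))
})
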