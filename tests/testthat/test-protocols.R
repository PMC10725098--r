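test_that("RSSM masking keeps exactly min(m, n_i) sites per mouth", {
  co <- make_cohort(list(c(2:15, 18:31), 2:11),
                    list(rep(0L, 168), rep(1L, 60)))
  masked <- apply_rssm(co, 84, seed = 11)
  kept <- vapply(masked$miss, function(m)
    sum(m != periomi:::MISS_NONSELECTED), 0L)
  expect_equal(kept, c(84L, 60L))   # min rule: 60-site mouth untouched
  expect_identical(masked$status[[2]], co$status[[2]])
  # m = 168 on a full dentition is the identity
  expect_identical(apply_rssm(co, 168, seed = 1)$status, co$status)
  expect_error(apply_rssm(co, 0), "1..168")
})

test_that("masking never alters kept statuses and is seed-reproducible", {
  co <- random_complete_cohort(8, seed = 21)
  m1 <- apply_rssm(co, 42, seed = 5)
  m2 <- apply_rssm(co, 42, seed = 5)
  expect_identical(m1$status, m2$status)
  for (i in seq_len(8)) {
    kept <- m1$miss[[i]] != periomi:::MISS_NONSELECTED
    expect_identical(m1$status[[i]][kept], co$status[[i]][kept])
  }
  # technical-missing sites are eligible for selection and stay technical
  co$status[[1]][3] <- NA_integer_
  co$miss[[1]][3] <- periomi:::MISS_TECHNICAL
  m3 <- apply_rssm(co, 168, seed = 2)
  expect_equal(m3$miss[[1]][3], periomi:::MISS_TECHNICAL)
  # masking a masked cohort is rejected
  expect_error(apply_rssm(m1, 84), "already carries nonselected")
})

test_that("each existing site is selected uniformly with probability m/n", {
  # one mouth with 3 teeth (18 sites), m = 6 -> inclusion prob 1/3
  co <- make_cohort(list(c(5, 9, 22)), list(rep(0L, 18)))
  reps <- 10000L
  counts <- integer(18)
  for (r in seq_len(reps)) {
    m <- apply_rssm(co, 6, seed = r)
    counts <- counts + (m$miss[[1]] != periomi:::MISS_NONSELECTED)
  }
  # chi-square goodness of fit against uniform inclusion
  expect_gt(stats::chisq.test(counts)$p.value, 0.001)
  expect_equal(sum(counts), reps * 6L)
})

test_that("cluster resampling retains duplicates and matches the source mean", {
  one <- make_cohort(list(2:4), list(rep(1L, 18)))
  rs <- resample_clusters(one, size = 3, seed = 1)
  expect_equal(periomi:::n_subjects(rs), 3L)
  expect_identical(rs$status[[2]], one$status[[1]])
  expect_error(resample_clusters(subset_empty <- structure(
    list(subjects = one$subjects[0, ], teeth = list(), status = list(),
         miss = list(), threshold = "CAL3+"), class = "perio_cohort")),
    "empty")
  expect_identical(resample_clusters(one, 5, seed = 9),
                   resample_clusters(one, 5, seed = 9))
  # law of large numbers: bootstrap-mean extent converges to source extent
  co <- random_complete_cohort(25, p = 0.3, seed = 2)
  e <- estimand("extent")
  src <- cohort_estimate(co, e)$point
  boots <- vapply(seq_len(2000), function(r)
    cohort_estimate(resample_clusters(co, seed = r), e)$point, 0)
  expect_lt(abs(mean(boots) - src), 3 * stats::sd(boots) / sqrt(2000))
})
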