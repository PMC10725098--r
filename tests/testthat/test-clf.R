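test_that("conditional means match the hand-derived pair formulas", {
  # exchangeable pair: mu 0.5/0.5, r = 0.5, y1 = 1 -> 0.75
  s <- exch_spec(0.5, 0.5, 2)
  expect_equal(clf_conditional_mean(s, 2, 1), 0.75)
  # general pair: lam2 = mu2 + r sqrt(v2/v1) (y1 - mu1)
  s2 <- clf_spec(c(0.2, 0.4), matrix(c(1, .3, .3, 1), 2))
  expect_equal(clf_conditional_mean(s2, 2, 1),
               0.4 + 0.3 * sqrt(0.24 / 0.16) * 0.8)
  # independence: conditional equals marginal for every history
  s3 <- clf_spec(c(.1, .6, .9), diag(3))
  expect_equal(clf_conditional_mean(s3, 3, c(1, 0)), 0.9)
  expect_equal(clf_conditional_mean(s3, 2, 0), 0.6)
})

test_that("exact pmf normalizes, reduces to product Bernoulli, and has
           matching moments when unclamped", {
  s1 <- clf_spec(0.3, matrix(1))
  pmf1 <- clf_exact_pmf(s1)
  expect_equal(sort(pmf1$prob), c(0.3, 0.7))
  s <- clf_spec(c(.2, .5, .8), diag(3))
  pmf <- clf_exact_pmf(s)
  expect_equal(sum(pmf$prob), 1, tolerance = 1e-12)
  ind <- apply(unclass(pmf$y), 1, function(y)
    prod(ifelse(y == 1, s$mu, 1 - s$mu)))
  expect_equal(pmf$prob, ind, tolerance = 1e-12)
  # feasible correlated spec reproduces (mu, R) exactly
  s2 <- exch_spec(c(0.3, 0.4, 0.5), 0.2)
  m <- periomi:::clf_pmf_moments(clf_exact_pmf(s2))
  expect_equal(m$mu, s2$mu, tolerance = 1e-10)
  expect_equal(m$R, s2$R, tolerance = 1e-10)
  expect_error(clf_exact_pmf(exch_spec(0.5, 0, 13)), "n <= 12")
})

test_that("sampling respects fixed prefixes and reproduces moments", {
  s <- exch_spec(c(.2, .4, .6, .3), 0.15)
  # all sites fixed -> output equals input
  expect_equal(clf_sample(s, fixed = c(1L, 0L, 1L, 0L), seed = 1),
               c(1L, 0L, 1L, 0L), ignore_attr = TRUE)
  # fixed entries must form a prefix
  expect_error(clf_sample(s, fixed = c(NA, 1L, NA, NA)), "prefix")
  # independence: empirical means match mu within 3 binomial SEs
  si <- clf_spec(c(.15, .5, .85), diag(3))
  Y <- clf_sample(si, ndraws = 50000, seed = 42)
  expect_true(all(abs(colMeans(Y) - si$mu) <
                    3 * sqrt(si$mu * (1 - si$mu) / 50000)))
  expect_equal(attr(Y, "clamp_rate"), 0)
  # exchangeable trio: pairwise correlations near 0.2 at 100k draws
  se <- exch_spec(0.5, 0.2, 3)
  Y2 <- clf_sample(se, ndraws = 100000, seed = 7)
  cors <- stats::cor(Y2)[upper.tri(diag(3))]
  expect_true(all(abs(cors - 0.2) < 0.015))
})

test_that("sampled outcome frequencies converge to the exact pmf", {
  s <- exch_spec(c(.25, .4, .55, .7), 0.25)
  pmf <- clf_exact_pmf(s)
  n <- 200000L
  Y <- clf_sample(s, ndraws = n, seed = 3)
  code <- as.integer(Y %*% 2^(0:3))
  emp <- tabulate(code + 1L, nbins = 16L) / n
  key <- as.integer(unclass(pmf$y) %*% 2^(0:3))
  tv <- sum(abs(emp[key + 1L] - pmf$prob)) / 2
  expect_lt(tv, 0.01)
})

test_that("conditioning order effects on a clamped spec are measured", {
  # a deliberately strained spec: low means with strong correlation forces
  # clamping; the distribution then depends (mildly) on conditioning order
  mu <- c(0.05, 0.1, 0.6, 0.7)
  R <- matrix(0.45, 4, 4); diag(R) <- 1
  s_fwd <- clf_spec(mu, R)
  ordr <- 4:1
  s_rev <- clf_spec(mu[ordr], R[ordr, ordr])
  m_fwd <- periomi:::clf_pmf_moments(clf_exact_pmf(s_fwd))
  m_rev <- periomi:::clf_pmf_moments(clf_exact_pmf(s_rev))
  dev <- max(abs(m_fwd$mu - m_rev$mu[order(ordr)]))
  # the deviation is a diagnostic, not an assumption: it must be finite and
  # bounded by the worst-case clamping distortion
  expect_true(is.finite(dev))
  expect_lt(dev, 0.1)
  # and the marginal means still track the nominal mu to first order
  expect_lt(max(abs(m_fwd$mu - mu)), 0.1)
})

test_that("the CLF specification constructor enforces shape and symmetry", {
  expect_error(clf_spec(c(.2, .3), diag(3)))
  R <- matrix(c(1, .4, .1, 1), 2)
  expect_error(clf_spec(c(.2, .3), R), "symmetric")
  R2 <- matrix(c(2, .1, .1, 1), 2)
  expect_error(clf_spec(c(.2, .3), R2), "unit diagonal")
})
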