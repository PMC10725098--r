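test_that("posterior draws center on theta-hat with the sandwich spread", {
  co <- random_complete_cohort(80, p = 0.25, seed = 12)
  fit <- fit_gee(co, mean_terms = "age", corr_terms = "same_tooth")
  # degenerate covariance returns theta-hat exactly
  fit0 <- fit; fit0$vcov[] <- 0
  expect_equal(draw_theta(fit0, seed = 1), fit$theta)
  # moments over many draws
  D <- draw_theta(fit, n = 10000, seed = 2)
  se <- sqrt(diag(fit$vcov))
  expect_true(all(abs(colMeans(D) - fit$theta) < 4 * se / sqrt(10000)))
  S <- stats::cov(D)
  expect_lt(norm(S - fit$vcov, "F") / norm(fit$vcov, "F"), 0.05)
  # a genuinely indefinite covariance is refused
  fitn <- fit
  fitn$vcov[1, 1] <- -1
  expect_error(draw_theta(fitn), "negative eigenvalues")
})

test_that("Rubin combining reproduces hand arithmetic and its invariants", {
  r <- mi_combine(c(10, 12), c(1, 3))
  expect_equal(r$point, 11)
  expect_equal(r$var_between, 2)
  expect_equal(r$var_within, 2)
  expect_equal(r$var_total, 2 + 1.5 * 2)
  # identical replicates: between-variance collapses
  r2 <- mi_combine(c(7, 7, 7), c(0.2, 0.2, 0.2))
  expect_equal(r2$var_between, 0)
  expect_equal(r2$var_total, r2$var_within)
  # permutation invariance
  p <- c(3, 9, 4, 6); v <- c(.1, .4, .2, .3)
  r3 <- mi_combine(p, v); r4 <- mi_combine(rev(p), rev(v))
  expect_equal(r3[c("point", "var_within", "var_between", "var_total")],
               r4[c("point", "var_within", "var_between", "var_total")])
  expect_error(mi_combine(5, 1), "at least 2")
  # the total can never undercut the within component
  withr::with_seed(33, replicate(50, {
    m <- sample(2:8, 1)
    r <- mi_combine(rnorm(m), rexp(m))
    expect_gte(r$var_total, r$var_within)
  }))
})

test_that("cluster bootstrap variance matches its analytic limit and is
           reproducible", {
  co <- random_complete_cohort(200, p = 0.25, seed = 15)
  e <- estimand("extent")
  vb <- boot_variance(co, e, B = 200, seed = 5)
  expect_identical(vb, boot_variance(co, e, B = 200, seed = 5))
  # with-replacement limit: sum((S-Sbar)^2)/K^2 for the equal-weight mean
  S <- subject_summaries(co, e)
  K <- length(S)
  limit <- sum((S - mean(S))^2) / K^2
  expect_lt(abs(vb - limit) / limit, 0.20)
  # constant statistic -> zero variance
  expect_equal(boot_variance(co, function(x) 42, B = 50, seed = 1), 0)
  one <- make_cohort(list(2:3), list(rep(0L, 12)))
  expect_warning(v1 <- boot_variance(one, e, B = 10), "single-cluster")
  expect_equal(v1, 0)
})

test_that("imputation completes every replicate, leaves observed data
           untouched, and respects M", {
  spec <- tiny_popspec()
  co <- generate_cohort(spec, K = 120, seed = 3)
  masked <- apply_rssm(co, 42, seed = 4)
  fit <- fit_gee(masked, mean_terms = character(0))
  imp <- impute_cohort(masked, fit, M = 5, seed = 6)
  expect_equal(imp$M, 5L)
  expect_length(imp$replicates, 5L)
  for (l in 1:5) {
    st <- imp$replicates[[l]]$status
    expect_false(anyNA(unlist(st)))
    for (i in seq_len(120)) {
      obs <- masked$miss[[i]] == 0L
      expect_identical(st[[i]][obs], masked$status[[i]][obs])
    }
  }
  expect_identical(impute_cohort(masked, fit, M = 3, seed = 9)$theta_draws,
                   impute_cohort(masked, fit, M = 3, seed = 9)$theta_draws)
  # a cohort with nothing missing reproduces itself in every replicate
  imp0 <- impute_cohort(co, fit, M = 2, seed = 1)
  expect_identical(imp0$replicates[[1]]$status, co$status)
  expect_error(impute_cohort(masked, fit, M = 1), "M >= 2")
})

test_that("imputed site frequencies track the model under independence", {
  # one subject, independence model, mu = 0.5 everywhere: imputed sites
  # average 0.5 over replicates
  co <- make_cohort(list(c(2:15, 18:31)),
                    list(as.integer(stats::runif(168) < 0.5)))
  masked <- apply_rssm(co, 84, seed = 2)
  fit <- structure(list(
    beta = c("(Intercept)" = 0), alpha = rep(0, 6),
    theta = c("(Intercept)" = 0,
              stats::setNames(rep(0, 6), paste0("corr:",
                c("(Intercept)", periomi:::CORR_TERMS)))),
    vcov = matrix(0, 7, 7), fit_alpha = TRUE,
    mean_terms = character(0),
    corr_terms = periomi:::CORR_TERMS, corr_cols = 0:5),
    class = "perio_gee")
  imp <- impute_cohort(masked, fit, M = 60, seed = 8)
  miss_idx <- which(masked$miss[[1]] > 0L)
  vals <- vapply(imp$replicates, function(r) mean(r$status[[1]][miss_idx]),
                 0)
  expect_lt(abs(mean(vals) - 0.5), 3 * 0.5 / sqrt(60 * length(miss_idx)))
})

test_that("MI-boot estimates combine per-estimand and shrink the between
           component when replicates agree", {
  spec <- tiny_popspec()
  co <- generate_cohort(spec, K = 100, seed = 5)
  masked <- apply_rssm(co, 84, seed = 6)
  fit <- fit_gee(masked, mean_terms = character(0))
  imp <- impute_cohort(masked, fit, M = 4, seed = 7)
  res <- mi_estimate(imp, list(estimand("extent"),
                               estimand("prevalence", 1)),
                     B = 60, seed = 8)
  expect_named(res, c("extent", "prevalence(h=1)"))
  for (r in res) {
    expect_gte(r$var_total, r$var_within)
    expect_equal(r$point, mean(r$per_replicate$estimate))
  }
  expect_gte(res[["prevalence(h=1)"]]$point, 0)
  expect_lte(res[["prevalence(h=1)"]]$point, 1)
})
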