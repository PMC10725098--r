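test_that("design builder emits one mean row per existing site and flags
           reference levels by omission", {
  co <- make_cohort(list(c(2, 3), 2:11), list(rep(0L, 12), rep(0L, 60)))
  d <- build_designs(co)
  expect_equal(nrow(d$X), 72L)
  expect_equal(colnames(d$X)[1], "(Intercept)")
  expect_equal(ncol(d$X), 16L)   # 1 + 5 + 5 + 1 + 4
  expect_false(any(grepl("disto-lingual", colnames(d$X))))
  expect_false(any(grepl("mandibular right", colnames(d$X))))
  expect_false(any(grepl("30-39", colnames(d$X))))
  expect_equal(d$logT, log(c(2, 10)))
})

test_that("with the correlation model fixed at zero the mean fit equals the
           independence logistic MLE", {
  co <- random_complete_cohort(60, p = 0.25, seed = 14)
  f0 <- fit_gee(co, fit_alpha = FALSE)
  d <- build_designs(co)
  g <- stats::glm.fit(d$X, d$y, family = stats::binomial())
  expect_lt(max(abs(f0$beta - g$coefficients)), 1e-6)
  expect_true(all(f0$alpha == 0))
  # intercept-only mean model recovers the pooled logit
  f1 <- fit_gee(co, mean_terms = character(0), fit_alpha = FALSE)
  expect_equal(unname(f1$beta), stats::qlogis(mean(d$y)),
               tolerance = 1e-9)
})

test_that("two-site clusters with an intercept-only correlation model give
           the closed-form moment estimate of alpha", {
  # each mouth: one tooth, 2 observed sites (4 masked), exchangeable
  set.seed(31)
  K <- 300
  teeth <- lapply(sample(c(2:15, 18:31), K, replace = TRUE), identity)
  status <- replicate(K, {
    z <- stats::rnorm(1)
    as.integer(stats::runif(6) < stats::plogis(-1 + 1.2 * z))
  }, simplify = FALSE)
  miss <- replicate(K, c(0L, 0L, rep(2L, 4)), simplify = FALSE)
  status <- lapply(status, function(s) { s[3:6] <- NA_integer_; s })
  co <- make_cohort(teeth, status, miss = miss)
  fit <- fit_gee(co, mean_terms = character(0), corr_terms = character(0))
  # alpha-hat must equal the mean over clusters of Z_i12 at the fitted mu
  mu <- stats::plogis(unname(fit$beta))
  v <- mu * (1 - mu)
  z <- vapply(co$status, function(s)
    (s[1] - mu) * (s[2] - mu) / v, 0)
  expect_equal(unname(fit$alpha), mean(z), tolerance = 1e-7)
})

test_that("estimates are invariant to cluster order and the sandwich scales
           as 1/K under cluster duplication", {
  co <- random_complete_cohort(40, p = 0.3, seed = 8)
  fit <- fit_gee(co)
  perm <- sample(seq_len(40))
  fit_p <- fit_gee(periomi:::subset_cohort(co, perm))
  expect_equal(fit_p$theta, fit$theta, tolerance = 1e-8)
  expect_equal(fit_p$vcov, fit$vcov, tolerance = 1e-6)
  # duplicating every cluster halves the sandwich exactly
  dup <- periomi:::subset_cohort(co, rep(seq_len(40), 2))
  fit_d <- fit_gee(dup)
  expect_equal(fit_d$theta, fit$theta, tolerance = 1e-8)
  expect_equal(fit_d$vcov, fit$vcov / 2, tolerance = 1e-6)
})

test_that("cluster weights rescale invariantly and enter the fit", {
  co <- random_complete_cohort(50, p = 0.3, seed = 18)
  co2 <- co; co2$subjects$weight <- rep(7, 50)
  f1 <- fit_gee(co); f2 <- fit_gee(co2)
  expect_equal(f1$theta, f2$theta, tolerance = 1e-8)
  # unequal weights move the estimate
  co3 <- co; co3$subjects$weight <- seq(0.2, 5, length.out = 50)
  f3 <- fit_gee(co3)
  expect_gt(max(abs(f3$beta - f1$beta)), 1e-4)
})

test_that("degenerate inputs are reported: separation and lone sites", {
  # outcome perfectly aligned with a site-type indicator -> separation
  co <- make_cohort(list(c(2:15, 18:31)),
                    list(as.integer(site_index()$site_type ==
                                      "distal-buccal")))
  co <- periomi:::subset_cohort(co, rep(1L, 20))
  expect_error(
    suppressWarnings(fit_gee(co, mean_terms = "site_type",
                             fit_alpha = FALSE)),
    "separation|converge")
  # a mouth with a single observed site draws a warning, not an error
  co2 <- random_complete_cohort(30, p = 0.3, seed = 4)
  co2$miss[[1]][2:length(co2$miss[[1]])] <- 2L
  co2$status[[1]][-1] <- NA_integer_
  expect_warning(fit_gee(co2, mean_terms = character(0),
                         corr_terms = character(0)),
                 "single observed site")
})

test_that("joint fit recovers truth from CLF-generated data (small n)", {
  spec <- tiny_popspec(intercept = -1, alpha = c(0.12, 0.2, 0.1, 0.05,
                                                 0.02, 0))
  co <- generate_cohort(spec, K = 600, seed = 77)
  fit <- fit_gee(co, mean_terms = character(0))
  # intercept of the mean model
  expect_lt(abs(fit$beta[["(Intercept)"]] - (-1)),
            3 * sqrt(fit$vcov[1, 1]))
  # correlation-category coefficients
  a_hat <- fit$alpha[c("(Intercept)", "same_tooth", "adjacent_same_ip",
                       "adjacent_diff_ip", "opposing")]
  a_se <- sqrt(diag(fit$vcov))[paste0("corr:", names(a_hat))]
  expect_true(all(abs(a_hat - spec$alpha[1:5]) < 3.5 * a_se))
})
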