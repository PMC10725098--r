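# Shared fixture builders (all fixtures are generated in code).

# a cohort built directly from per-subject tooth sets and statuses
make_cohort <- function(teeth, status, weight = NULL, age = NULL,
                        miss = NULL) {
  K <- length(teeth)
  if (is.null(weight)) weight <- rep(1, K)
  if (is.null(age)) age <- rep("30-39", K)
  perio_cohort(
    data.frame(subject_id = paste0("S", seq_len(K)), weight = weight,
               age_group = age, stringsAsFactors = FALSE),
    teeth, status, miss)
}

# a complete single-age cohort with random dentitions and iid site status
random_complete_cohort <- function(K, p = 0.2, seed = 1) {
  withr::with_seed(seed, {
    teeth <- lapply(seq_len(K), function(i)
      sort(sample(c(2:15, 18:31), sample(3:28, 1))))
    status <- lapply(teeth, function(t)
      rbinom(6L * length(t), 1L, p))
    ages <- sample(c("30-39", "40-49", "50-59", "60-69", "70+"), K,
                   replace = TRUE)
    make_cohort(teeth, status, age = ages)
  })
}

# small population spec with known truth for recovery-style tests
tiny_popspec <- function(intercept = -1.2, alpha = c(0.1, 0.2, 0.15,
                                                     0.05, 0.02, 0)) {
  spec <- nhanes_like_preset()
  spec$beta[] <- 0
  spec$beta["(Intercept)"] <- intercept
  spec$alpha <- alpha
  spec$tech_missing_rate <- 0
  spec
}

# exchangeable CLF spec helper
exch_spec <- function(mu, r, n = length(mu)) {
  if (length(mu) == 1L) mu <- rep(mu, n)
  R <- matrix(r, n, n); diag(R) <- 1
  clf_spec(mu, R)
}
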