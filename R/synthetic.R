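#' Specify a synthetic full-mouth population
#'
#' Defines the generating distribution of a synthetic cohort of mouths
#' with known truth: a categorical distribution of tooth counts, an
#' age-group distribution, and a true parameter vector on exactly the
#' parameterization of the imputation model (logistic mean model over
#' site type, sextant, log teeth and age; linear correlation model over
#' pair categories and log teeth).  Because the generator shares the
#' model family — and the CLF sampler — with the imputer, recovery tests
#' against it are congenial by construction; the small-`n` enumeration
#' oracle provides a non-shared-code cross-check.
#'
#' @param beta named numeric vector of mean-model coefficients in the
#'   order produced by [build_designs()] (16 values for the full model).
#' @param alpha numeric vector of the six correlation-model coefficients:
#'   intercept (different-teeth reference), same tooth, adjacent same IP,
#'   adjacent different IP, opposing, log teeth.
#' @param teeth_probs probabilities for tooth counts 1..28 (normalized).
#' @param age_probs probabilities for the five age groups (normalized).
#' @param weight_scheme `"unit"` (all 1, a simple random sample) or
#'   `"gamma"` (mean-1 gamma draws emulating unequal design weights).
#' @param tech_missing_rate per-site probability of missingness for
#'   technical reasons (default 0.005, i.e. under 1%).
#' @return object of class `perio_popspec`.
#' @export
population_spec <- function(beta, alpha, teeth_probs, age_probs,
                            weight_scheme = c("unit", "gamma"),
                            tech_missing_rate = 0.005) {
  weight_scheme <- match.arg(weight_scheme)
  stopifnot(length(alpha) == 6L, length(teeth_probs) == 28L,
            length(age_probs) == 5L, all(teeth_probs >= 0),
            all(age_probs >= 0), sum(teeth_probs) > 0, sum(age_probs) > 0,
            tech_missing_rate >= 0, tech_missing_rate < 1)
  teeth_probs <- teeth_probs / sum(teeth_probs)
  age_probs <- age_probs / sum(age_probs)
  # implied pairwise correlations must lie inside (-1, 1) for every
  # attainable tooth count and pair category
  support <- which(teeth_probs > 0)
  for (n_teeth in range(support)) {
    rho <- rho_by_cat(alpha, 0:5, log(n_teeth), rho_max = Inf)
    if (any(abs(rho) >= 1))
      stop("alpha implies pairwise correlation outside (-1, 1) at ",
           n_teeth, " teeth")
  }
  structure(list(beta = beta, alpha = alpha, teeth_probs = teeth_probs,
                 age_probs = age_probs, weight_scheme = weight_scheme,
                 tech_missing_rate = tech_missing_rate),
            class = "perio_popspec")
}

#' Generate a synthetic full-mouth cohort
#'
#' Draws `K` mouths from a [population_spec()]: age group, tooth count and
#' a uniformly random subset of present teeth, then the full site vector
#' from the conditional linear family distribution implied by the true
#' coefficients (canonical site order as conditioning order, no fixed
#' sites), and finally sprinkles technical missingness.  Per-subject
#' random substreams are derived from `seed`, so the same seed reproduces
#' the same cohort regardless of generation order.
#'
#' @param spec a `perio_popspec`.
#' @param K number of mouths.
#' @param seed integer seed.
#' @return a full-mouth `perio_cohort`.
#' @export
generate_cohort <- function(spec, K, seed = NULL) {
  stopifnot(inherits(spec, "perio_popspec"), K >= 1)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  draws <- with_seed(substream_seed(seed, 20L), {
    list(age = sample(PERIO_AGE_GROUPS, K, replace = TRUE,
                      prob = spec$age_probs),
         nt = sample.int(28L, K, replace = TRUE, prob = spec$teeth_probs),
         w = if (spec$weight_scheme == "gamma")
               stats::rgamma(K, shape = 4, rate = 4) else rep(1, K))
  })
  teeth <- lapply(seq_len(K), function(i)
    with_seed(substream_seed(seed, 21L, i),
              sort(sample(PERIO_TEETH, draws$nt[i]))))
  skeleton <- perio_cohort(
    data.frame(subject_id = sprintf("S%05d", seq_len(K)),
               weight = draws$w, age_group = draws$age,
               stringsAsFactors = FALSE),
    teeth,
    lapply(draws$nt, function(n) rep(0L, 6L * n)))
  d <- build_designs(skeleton)
  mu <- stats::plogis(as.numeric(d$X %*% spec$beta))
  for (i in seq_len(K)) {
    a <- d$ptr[i] + 1L; b <- d$ptr[i + 1L]
    rho <- rho_by_cat(spec$alpha, 0:5, d$logT[i])
    res <- with_seed(substream_seed(seed, 22L, i),
                     clf_draw_engine(mu[a:b], d$tooth[a:b], d$ip[a:b],
                                     d$jaw[a:b], d$opp[a:b], rho,
                                     rep(-1L, b - a + 1L), 1e-6, 1e-8,
                                     TRUE))
    if (!isTRUE(res$ok))
      stop("infeasible correlation structure while generating subject ", i)
    y <- as.integer(res$y)
    if (spec$tech_missing_rate > 0) {
      tech <- with_seed(substream_seed(seed, 23L, i),
                        runif(length(y)) < spec$tech_missing_rate)
      if (any(tech)) {
        y[tech] <- NA_integer_
        skeleton$miss[[i]][tech] <- MISS_TECHNICAL
      }
    }
    skeleton$status[[i]] <- y
  }
  skeleton
}

#' A frozen NHANES-like population preset
#'
#' A documented [population_spec()] whose full-mouth cohort resembles the
#' adult (30+) US population in broad strokes: tooth counts concentrated
#' near 25-28, disease probability higher at interproximal than mid
#' sites, higher in posterior sextants, increasing steeply with age and
#' with decreasing tooth count, and within-mouth correlations strongest
#' on the same tooth, then across a shared interproximal space.  The
#' coefficients were calibrated once by simulation (see
#' `scripts/calibrate_preset.R`) so that the full-mouth mean extent is
#' about 19 sites and the prevalences of one-or-more and two-or-more
#' affected sites about 0.89 and 0.82 (the frozen calibration values are
#' in the `calibration` element), and are not tuned thereafter.
#'
#' @return a `perio_popspec` with an extra `calibration` element
#'   (`mean_extent`, `prevalence1`, `prevalence2`, `K`, `seed` used for
#'   calibration).
#' @export
nhanes_like_preset <- function() {
  beta <- c(
    "(Intercept)" = 0.22,
    "site_distal-buccal" = 0.05, "site_buccal" = -0.40,
    "site_mesio-buccal" = -0.05, "site_mesio-lingual" = -0.10,
    "site_lingual" = -0.45,
    "sextant_maxillary right posterior" = 0.05,
    "sextant_maxillary anterior" = -0.35,
    "sextant_maxillary left posterior" = 0.05,
    "sextant_mandibular left posterior" = 0.00,
    "sextant_mandibular anterior" = -0.25,
    "log_teeth" = -0.80,
    "age_40-49" = 0.45, "age_50-59" = 0.85, "age_60-69" = 1.20,
    "age_70+" = 1.50)
  alpha <- c(0.28, 0.24, 0.16, 0.07, 0.03, -0.03)
  teeth_probs <- c(0.002, 0.002, 0.003, 0.004, 0.004, 0.005, 0.005,
                   0.006, 0.007, 0.008, 0.009, 0.010, 0.011, 0.013,
                   0.015, 0.018, 0.020, 0.025, 0.030, 0.035, 0.040,
                   0.045, 0.050, 0.070, 0.090, 0.110, 0.140, 0.280)
  age_probs <- c(0.25, 0.24, 0.22, 0.17, 0.12)
  spec <- population_spec(beta, alpha, teeth_probs, age_probs,
                          weight_scheme = "unit",
                          tech_missing_rate = 0.005)
  spec$calibration <- list(mean_extent = 19.24, prevalence1 = 0.891,
                           prevalence2 = 0.815, K = 3621L,
                           seed = 20260101L)
  spec
}
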