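#' Draw imputation parameters from their approximate posterior
#'
#' Draws \eqn{\theta^* \sim \mathrm{MVN}(\hat\theta, V(\hat\theta))}, the
#' approximate posterior predictive distribution of the joint mean and
#' correlation coefficients.  The covariance is projected to positive
#' semi-definite (eigenvalues below zero clipped, tolerance 1e-10 relative)
#' before factorization; genuinely negative eigenvalues beyond the
#' tolerance are an error.
#'
#' @param fit a `perio_gee` fit.
#' @param n number of draws.
#' @param seed optional integer seed.
#' @return for `n = 1` a named vector; otherwise an `n x length(theta)`
#'   matrix.
#' @export
draw_theta <- function(fit, n = 1L, seed = NULL) {
  stopifnot(inherits(fit, "perio_gee"))
  theta <- fit$theta
  V <- fit$vcov
  eg <- eigen(V, symmetric = TRUE)
  scale <- max(abs(eg$values), 1e-300)
  if (min(eg$values) < -1e-8 * scale)
    stop("parameter covariance has negative eigenvalues beyond tolerance")
  d <- pmax(eg$values, 0)
  A <- eg$vectors %*% (sqrt(d) * t(eg$vectors))   # symmetric square root
  Z <- with_seed(seed, matrix(rnorm(n * length(theta)), n))
  draws <- sweep(Z %*% A, 2L, theta, `+`)
  colnames(draws) <- names(theta)
  if (n == 1L) draws[1L, ] else draws
}

#' Multiply-impute nonselected sites of a masked cohort
#'
#' Creates `M` pseudo-complete copies of a masked cohort.  For each
#' replicate one parameter vector is drawn from the posterior of the
#' fitted imputation model (shared by all mouths in that replicate), each
#' mouth's marginal means and pairwise correlation matrix are rebuilt from
#' the drawn coefficients, and every missing site (nonselected by the
#' protocol, or unmeasured for technical reasons) is drawn from the
#' conditional linear family distribution conditioned on the mouth's
#' observed sites (observed sites first in the conditioning order, missing
#' sites following in canonical order).  Observed 0/1 statuses are carried
#' into every replicate unchanged.
#'
#' @param masked a masked `perio_cohort`.
#' @param fit the `perio_gee` fit of the imputation model (usually on the
#'   same masked cohort).
#' @param M number of imputation replicates (default 25).
#' @param seed integer master seed; per-(replicate, subject) substreams
#'   make the result independent of evaluation order.
#' @param eps clamping tolerance for conditional means (default 1e-6).
#' @return object of class `perio_imputation`: list with `replicates`
#'   (list of `M` complete cohorts), `theta_draws` (`M x` npar matrix),
#'   `clamp_rate` (per replicate, share of drawn conditionals clamped),
#'   `n_unconditional` (mouths imputed with no observed sites), `M`,
#'   `seed`.
#' @export
impute_cohort <- function(masked, fit, M = 25L, seed = NULL, eps = 1e-6) {
  stopifnot(inherits(masked, "perio_cohort"), inherits(fit, "perio_gee"),
            M >= 2L)
  if (!fit$fit_alpha)
    stop("imputation requires a fitted correlation model (fit_alpha = TRUE)")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  d <- build_designs(masked, mean_terms = fit$mean_terms)
  K <- n_subjects(masked)
  p <- length(fit$beta)
  need <- vapply(masked$miss, function(m) any(m > 0L), logical(1L))
  n_uncond <- sum(vapply(masked$miss, function(m) all(m > 0L), logical(1L)))
  # stack sites observed-first within each cluster (the conditioning order)
  perm <- unlist(lapply(seq_len(K), function(i)
    d$ptr[i] + order(masked$miss[[i]] > 0L)))
  fixed_p <- unlist(masked$status)[perm]
  fixed_p[is.na(fixed_p)] <- -1L
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)

  theta_draws <- matrix(NA_real_, M, length(fit$theta),
                        dimnames = list(NULL, names(fit$theta)))
  replicates <- vector("list", M)
  clamp_rate <- numeric(M)
  cl_idx <- rep(seq_len(K), n_sites(masked))
  for (l in seq_len(M)) {
    th <- draw_theta(fit, seed = substream_seed(seed, 2L, l))
    theta_draws[l, ] <- th
    beta_l <- th[seq_len(p)]
    alpha_l <- th[-seq_len(p)]
    mu <- stats::plogis(as.numeric(d$X %*% beta_l))
    rho <- t(vapply(seq_len(K), function(i)
      rho_by_cat(alpha_l, fit$corr_cols, d$logT[i]), numeric(5L)))
    seeds <- vapply(seq_len(K), function(i)
      substream_seed(seed, 3L, l, i), 0L)
    res <- clf_impute_replicate(mu[perm], d$tooth[perm], d$ip[perm],
                                d$jaw[perm], d$opp[perm], rho,
                                as.integer(fixed_p),
                                as.integer(d$ptr), as.integer(need),
                                seeds, eps, 1e-8)
    if (!isTRUE(res$ok))
      stop("CLF covariance for subject ",
           masked$subjects$subject_id[res$fail_cluster],
           " is singular even after ridge and repair")
    y <- as.integer(res$y)[inv]
    rep_cohort <- masked
    rep_cohort$status <- split(y, cl_idx)
    names(rep_cohort$status) <- NULL
    rep_cohort$miss <- lapply(lengths(rep_cohort$status),
                              function(n) rep(MISS_OBSERVED, n))
    replicates[[l]] <- rep_cohort
    clamp_rate[l] <- if (res$n_drawn > 0) res$n_clamped / res$n_drawn else 0
  }
  structure(list(replicates = replicates, theta_draws = theta_draws,
                 clamp_rate = clamp_rate, n_unconditional = n_uncond,
                 M = M, seed = seed, source = masked),
            class = "perio_imputation")
}

#' @export
print.perio_imputation <- function(x, ...) {
  cat("perio_imputation: M = ", x$M, " complete replicates of ",
      n_subjects(x$source), " mouths\n", sep = "")
  cat("  mean clamp rate of drawn conditionals: ",
      signif(mean(x$clamp_rate), 3), "\n", sep = "")
  if (x$n_unconditional > 0)
    cat("  ", x$n_unconditional,
        " mouth(s) imputed unconditionally (no observed sites)\n", sep = "")
  invisible(x)
}

#' Combine per-replicate estimates by Rubin's rules
#'
#' The combined point estimate is the average of the `M` replicate
#' estimates; the total variance is
#' \eqn{\hat V = V_W + (1 + 1/M) V_B} with the within-imputation variance
#' \eqn{V_W} the average of the replicate variances and the
#' between-imputation variance \eqn{V_B} the sample variance of the
#' replicate estimates (divisor `M - 1`).
#'
#' @param points numeric vector of per-replicate estimates (length `M >= 2`).
#' @param variances per-replicate (within-imputation) variance estimates.
#' @return object of class `mi_estimate` with `point`, `var_within`,
#'   `var_between`, `var_total`, `M`, `per_replicate`.
#' @export
mi_combine <- function(points, variances) {
  M <- length(points)
  if (M < 2L) stop("Rubin combining requires at least 2 replicates")
  stopifnot(length(variances) == M, all(is.finite(points)),
            all(is.finite(variances)), all(variances >= 0))
  point <- mean(points)
  v_b <- sum((point - points)^2) / (M - 1)
  v_w <- mean(variances)
  structure(list(point = point, var_within = v_w, var_between = v_b,
                 var_total = v_w + (1 + 1 / M) * v_b, M = M,
                 per_replicate = data.frame(estimate = points,
                                            variance = variances)),
            class = "mi_estimate")
}

#' @export
print.mi_estimate <- function(x, ...) {
  cat("MI estimate: ", signif(x$point, 6), "  (total variance ",
      signif(x$var_total, 4), " = within ", signif(x$var_within, 4),
      " + (1 + 1/M) x between ", signif(x$var_between, 4), "; M = ",
      x$M, ")\n", sep = "")
  invisible(x)
}

#' Cluster-bootstrap variance of a cohort statistic
#'
#' Resamples mouths (clusters) with replacement `B` times and returns the
#' sample variance (divisor `B - 1`) of the statistic about its own
#' bootstrap mean — the within-imputation variance of the MI-boot
#' procedure when applied to a completed data set.
#'
#' @param cohort a complete `perio_cohort`.
#' @param statistic a [estimand()] (the weighted cohort estimate is then
#'   bootstrapped) or a function taking a cohort and returning a scalar.
#' @param B number of bootstrap samples (default 200).
#' @param seed optional integer seed.
#' @return the bootstrap variance estimate.
#' @export
boot_variance <- function(cohort, statistic, B = 200L, seed = NULL) {
  stopifnot(inherits(cohort, "perio_cohort"), B >= 2L)
  K <- n_subjects(cohort)
  if (K == 1L) {
    warning("single-cluster cohort: bootstrap variance is 0")
    return(0)
  }
  vals <- with_seed(seed, {
    if (inherits(statistic, "perio_estimand")) {
      S <- subject_summaries(cohort, statistic)
      w <- cohort$subjects$weight
      vapply(seq_len(B), function(b) {
        idx <- sample.int(K, K, replace = TRUE)
        sum(w[idx] * S[idx]) / sum(w[idx])
      }, 0)
    } else {
      vapply(seq_len(B), function(b)
        statistic(resample_clusters(cohort, K)), 0)
    }
  })
  sum((vals - mean(vals))^2) / (B - 1)
}

#' MI-boot estimates from an imputed cohort
#'
#' For each imputation replicate, computes the weighted cohort estimate of
#' each requested estimand and its cluster-bootstrap variance (`B`
#' resamples), then combines across replicates by Rubin's rules
#' ([mi_combine()]).  Bootstrap index sets are drawn independently per
#' replicate.
#'
#' @param imputation a `perio_imputation`.
#' @param estimands a single [estimand()] or list of them.
#' @param B bootstrap samples per replicate (default 200).
#' @param seed optional integer master seed.
#' @return a named list of `mi_estimate` objects (names from
#'   `format(estimand)`).
#' @export
mi_estimate <- function(imputation, estimands, B = 200L, seed = NULL) {
  stopifnot(inherits(imputation, "perio_imputation"))
  if (inherits(estimands, "perio_estimand")) estimands <- list(estimands)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  M <- imputation$M
  out <- vector("list", length(estimands))
  names(out) <- vapply(estimands, format, "")
  for (e in seq_along(estimands)) {
    est <- estimands[[e]]
    pts <- numeric(M); vars <- numeric(M)
    for (l in seq_len(M)) {
      rep_cohort <- imputation$replicates[[l]]
      pts[l] <- cohort_estimate(rep_cohort, est)$point
      vars[l] <- boot_variance(rep_cohort, est, B = B,
                               seed = substream_seed(seed, 4L, l, e))
    }
    out[[e]] <- mi_combine(pts, vars)
  }
  out
}
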