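#' Percent relative bias of replicate estimates
#'
#' Mean over replicates of `(estimate - gold) / gold * 100`.
#'
#' @param estimates numeric vector of replicate estimates.
#' @param gold the gold-standard (full-mouth) estimate; must be nonzero.
#' @return percent relative bias.
#' @export
pct_relative_bias <- function(estimates, gold) {
  stopifnot(length(gold) == 1L, is.finite(gold))
  if (gold == 0) stop("gold-standard estimate is zero; relative bias ",
                      "undefined")
  mean((estimates - gold) / gold) * 100
}

#' Percent relative efficiency of replicate variance estimates
#'
#' Ratio of the full-mouth variance estimate to the average replicate
#' variance estimate, times 100; values below 100 quantify information
#' lost to the partial-mouth protocol.
#'
#' @param fm_variance the full-mouth variance estimate.
#' @param variance_estimates per-replicate variance estimates.
#' @return percent relative efficiency.
#' @export
pct_relative_efficiency <- function(fm_variance, variance_estimates) {
  mv <- mean(variance_estimates)
  if (!is.finite(mv) || mv <= 0) stop("mean variance estimate must be ",
                                      "positive")
  fm_variance / mv * 100
}

#' Percent relative bias of the variance estimator
#'
#' Compares the average variance estimate with the Monte Carlo variance of
#' the point estimates (divisor `R - 1`):
#' `(mean(variances) - mc_var) / mc_var * 100`.
#'
#' @param variance_estimates per-replicate variance estimates.
#' @param point_estimates per-replicate point estimates (at least 2).
#' @return percent relative bias of the variance estimator.
#' @export
pct_relative_bias_variance <- function(variance_estimates, point_estimates) {
  stopifnot(length(point_estimates) >= 2L)
  mc <- stats::var(point_estimates)
  if (mc == 0) stop("Monte Carlo variance of the point estimates is zero")
  (mean(variance_estimates) - mc) / mc * 100
}

# Full-mouth estimate tolerating the (<1%) technical-missing sites real
# full-mouth examinations carry: unmeasured sites count as unaffected,
# exactly as the direct full-mouth calculation treats them.  Identical to
# cohort_estimate() on complete data.
fm_estimate <- function(cohort, est) {
  s <- vapply(cohort$status, function(x) sum(x, na.rm = TRUE), 0L)
  S <- if (est$kind == "extent") as.numeric(s) else as.numeric(s >= est$h)
  w <- cohort$subjects$weight
  sw <- sum(w)
  K <- length(S)
  point <- sum(w * S) / sw
  variance <- if (K > 1L)
    K / (K - 1) * sum(w^2 * (S - point)^2) / sw^2 else 0
  list(point = point, variance = variance, K = K)
}

#' Simulation evaluation of partial-mouth estimators
#'
#' Repeats the full evaluation cycle of the method: resample mouths with
#' replacement from a full-mouth cohort, mask with a random site selection
#' protocol, fit the imputation model, multiply impute, and compute MI-boot
#' extent/prevalence estimates — then summarises the replicates against
#' the gold standard (the estimate on the source full-mouth cohort) with
#' percent relative bias, average and Monte Carlo variance, percent
#' relative efficiency, and percent relative bias of the variance
#' estimator.  With `m = NULL` the full-mouth arm is evaluated instead (no
#' masking or imputation; Taylor variances).  The biased standard method
#' (full-mouth case definition applied directly to the masked data) is
#' computed on the same replicates for comparison.
#'
#' @param cohort complete full-mouth `perio_cohort`.
#' @param m sites per mouth for the RSSM mask, or `NULL` for the
#'   full-mouth arm.
#' @param estimands list of [estimand()]s (default: extent,
#'   prevalence h=1, prevalence h=2).
#' @param reps number of evaluation replicates (the reference analysis
#'   uses 500).
#' @param M imputation replicates per evaluation replicate (default 25).
#' @param B bootstrap samples per imputation replicate (default 200).
#' @param seed integer master seed; every replicate derives its own
#'   substreams, so results do not depend on scheduling.
#' @param verbose print progress every 10 replicates.
#' @return object of class `perio_eval`: `metrics` (one row per
#'   estimand), `per_rep` (replicate-level estimates), `gold`, `settings`,
#'   `n_failed` (replicates skipped after a model-fitting failure) and
#'   `failures` (their error messages).
#' @export
run_evaluation <- function(cohort, m = NULL,
                           estimands = list(estimand("extent"),
                                            estimand("prevalence", 1),
                                            estimand("prevalence", 2)),
                           reps = 500L, M = 25L, B = 200L, seed = NULL,
                           verbose = FALSE) {
  stopifnot(inherits(cohort, "perio_cohort"), reps >= 2L)
  if (inherits(estimands, "perio_estimand")) estimands <- list(estimands)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  enames <- vapply(estimands, format, "")
  gold <- lapply(estimands, function(e) fm_estimate(cohort, e))
  names(gold) <- enames

  ne <- length(estimands)
  pts <- matrix(NA_real_, reps, ne, dimnames = list(NULL, enames))
  vars <- pts
  stds <- pts
  failures <- character(0)
  for (r in seq_len(reps)) {
    boot <- resample_clusters(cohort, seed = substream_seed(seed, 10L, r))
    if (is.null(m)) {
      for (e in seq_len(ne)) {
        ce <- fm_estimate(boot, estimands[[e]])
        pts[r, e] <- ce$point; vars[r, e] <- ce$variance
        stds[r, e] <- ce$point
      }
    } else {
      masked <- apply_rssm(boot, m, seed = substream_seed(seed, 11L, r))
      fit <- tryCatch(fit_gee(masked),
                      error = function(err) conditionMessage(err))
      if (is.character(fit)) {
        failures <- c(failures, sprintf("replicate %d: %s", r, fit))
        next
      }
      imp <- impute_cohort(masked, fit, M = M,
                           seed = substream_seed(seed, 12L, r))
      res <- mi_estimate(imp, estimands, B = B,
                         seed = substream_seed(seed, 13L, r))
      for (e in seq_len(ne)) {
        pts[r, e] <- res[[e]]$point
        vars[r, e] <- res[[e]]$var_total
        stds[r, e] <- standard_partial_estimate(masked, estimands[[e]])
      }
    }
    if (verbose && r %% 10L == 0L)
      message("evaluation replicate ", r, "/", reps)
  }
  done <- stats::complete.cases(pts)
  if (sum(done) < 2L)
    stop("fewer than 2 successful evaluation replicates")
  metrics <- do.call(rbind, lapply(seq_len(ne), function(e) {
    g <- gold[[e]]
    data.frame(
      estimand = enames[e],
      protocol = if (is.null(m)) "FMPE" else sprintf("RSSM %d", m),
      gold_estimate = g$point,
      avg_estimate = mean(pts[done, e]),
      pct_rel_bias = pct_relative_bias(pts[done, e], g$point),
      avg_variance = mean(vars[done, e]),
      mc_variance = stats::var(pts[done, e]),
      pct_rel_efficiency = pct_relative_efficiency(g$variance,
                                                   vars[done, e]),
      pct_rel_bias_variance = pct_relative_bias_variance(vars[done, e],
                                                         pts[done, e]),
      std_avg_estimate = mean(stds[done, e]),
      std_pct_rel_bias = pct_relative_bias(stds[done, e], g$point),
      n_replicates = sum(done),
      stringsAsFactors = FALSE)
  }))
  structure(list(metrics = metrics,
                 per_rep = list(points = pts, variances = vars,
                                standard = stds),
                 gold = gold,
                 settings = list(m = m, reps = reps, M = M, B = B,
                                 seed = seed),
                 n_failed = reps - sum(done), failures = failures),
            class = "perio_eval")
}

#' @export
print.perio_eval <- function(x, ...) {
  cat("Evaluation (", x$metrics$protocol[1], "), ",
      x$metrics$n_replicates[1], " replicates",
      if (x$n_failed > 0) sprintf(" (%d failed, skipped)", x$n_failed),
      ":\n", sep = "")
  print(x$metrics[, c("estimand", "gold_estimate", "avg_estimate",
                      "pct_rel_bias", "avg_variance", "mc_variance",
                      "pct_rel_efficiency", "pct_rel_bias_variance")],
        row.names = FALSE, digits = 4)
  invisible(x)
}
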