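#' Define an estimand (extent or prevalence)
#'
#' Extent is the number of sites in a mouth meeting the disease threshold,
#' \eqn{S_{i} = \sum_j Y_{ij}}; its population mean is the extent estimand.
#' Prevalence uses the site-count case definition
#' \eqn{S_{i} = I(\sum_j Y_{ij} \ge h)}: with `h = 1` the case definition
#' is one or more affected sites, with `h = 2` two or more.
#'
#' @param kind `"extent"` or `"prevalence"`.
#' @param h site-count threshold for prevalence (ignored for extent).
#' @return object of class `perio_estimand`.
#' @export
estimand <- function(kind = c("extent", "prevalence"), h = 1L) {
  kind <- match.arg(kind)
  if (kind == "prevalence") stopifnot(length(h) == 1L, h >= 1)
  structure(list(kind = kind, h = if (kind == "prevalence") as.integer(h)
                                  else NA_integer_),
            class = "perio_estimand")
}

#' @export
format.perio_estimand <- function(x, ...) {
  if (x$kind == "extent") "extent" else sprintf("prevalence(h=%d)", x$h)
}

#' @export
print.perio_estimand <- function(x, ...) {
  cat(format(x), "\n"); invisible(x)
}

#' Per-mouth disease summaries
#'
#' The subject-level summary statistic of a complete mouth: the count of
#' affected sites (extent) or the case indicator (prevalence).
#'
#' @param cohort a complete `perio_cohort` (all existing sites 0/1).
#' @param est a [estimand()].
#' @return numeric vector, one value per mouth.
#' @export
subject_summaries <- function(cohort, est) {
  stopifnot(inherits(cohort, "perio_cohort"), inherits(est, "perio_estimand"))
  if (!is_complete_cohort(cohort))
    stop("cohort has missing site statuses; impute before summarising")
  s <- vapply(cohort$status, sum, 0L)
  if (est$kind == "extent") as.numeric(s) else as.numeric(s >= est$h)
}

#' Weighted cohort estimate with Taylor-linearized variance
#'
#' The weighted ratio estimator of the population mean summary,
#' \eqn{\hat\tau = \sum_i w_i S_i / \sum_i w_i}, with the single-stage
#' with-replacement Taylor linearization variance
#' \eqn{\frac{K}{K-1} \sum_i w_i^2 (S_i - \hat\tau)^2 / (\sum_i w_i)^2}.
#' With equal weights this reduces to the classical sampling variance of a
#' mean, \eqn{\sum_i (S_i - \bar S)^2 / \{K(K-1)\}}.
#'
#' @param cohort a complete `perio_cohort`.
#' @param est a [estimand()].
#' @return list with `point`, `variance`, `K`.
#' @export
cohort_estimate <- function(cohort, est) {
  S <- subject_summaries(cohort, est)
  w <- cohort$subjects$weight
  sw <- sum(w)
  if (sw <= 0) stop("total weight must be positive")
  K <- length(S)
  point <- sum(w * S) / sw
  variance <- if (K > 1L)
    K / (K - 1) * sum(w^2 * (S - point)^2) / sw^2 else 0
  list(point = point, variance = variance, K = K)
}

#' Standard partial-mouth estimate (the biased baseline)
#'
#' Applies the full-mouth case definition directly to the observed sites of
#' a masked cohort, treating every missing site as healthy.  Because a
#' subject with disease can have no diseased site selected while a healthy
#' subject can never appear diseased (specificity 100%, sensitivity below
#' 100%), this estimator systematically underestimates both extent and
#' prevalence; it is the comparator the imputation approach improves on.
#'
#' @param cohort a (masked) `perio_cohort`.
#' @param est a [estimand()].
#' @return the weighted point estimate.
#' @export
standard_partial_estimate <- function(cohort, est) {
  stopifnot(inherits(cohort, "perio_cohort"), inherits(est, "perio_estimand"))
  s <- vapply(cohort$status, function(x) sum(x, na.rm = TRUE), 0L)
  S <- if (est$kind == "extent") as.numeric(s) else as.numeric(s >= est$h)
  w <- cohort$subjects$weight
  sum(w * S) / sum(w)
}
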