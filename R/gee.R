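CORR_TERMS <- c("same_tooth", "adjacent_same_ip", "adjacent_diff_ip",
                "opposing", "log_teeth")
MEAN_TERMS <- c("site_type", "sextant", "log_teeth", "age")

# fixed per-site part of the mean design (site-type and sextant indicators
# with disto-lingual and mandibular-right-posterior reference levels)
site_design_block <- function() {
  if (!is.null(.periomi_env$site_block)) return(.periomi_env$site_block)
  si <- site_index()
  st <- stats::model.matrix(~ site_type, data = si,
    contrasts.arg = list(site_type = stats::contr.treatment(
      levels(si$site_type), base = 6L)))[, -1, drop = FALSE]
  colnames(st) <- paste0("site_", PERIO_SITE_TYPES[1:5])
  sx <- stats::model.matrix(~ sextant, data = si,
    contrasts.arg = list(sextant = stats::contr.treatment(
      levels(si$sextant), base = 6L)))[, -1, drop = FALSE]
  colnames(sx) <- paste0("sextant_", PERIO_SEXTANTS[1:5])
  blk <- cbind(st, sx)
  .periomi_env$site_block <- blk
  blk
}

#' Build mean- and correlation-model design structures for a cohort
#'
#' Produces the stacked per-site mean design (intercept, five site-type
#' indicators, five sextant indicators, log number of teeth, four age-group
#' indicators; reference levels disto-lingual, mandibular right posterior
#' and ages 30-39) and the per-site attributes from which every pair's
#' correlation-model category (same tooth / adjacent sharing an
#' interproximal space / adjacent not sharing it / vertically opposing /
#' other, reference) is derived.  One mean row exists for every site of
#' every present tooth; model fitting uses the observed subset, imputation
#' the full set.
#'
#' @param cohort a `perio_cohort`.
#' @param mean_terms character subset of
#'   `c("site_type", "sextant", "log_teeth", "age")`; the intercept is
#'   always included.
#' @return a list of stacked design components (class
#'   `perio_designs`).
#' @export
build_designs <- function(cohort, mean_terms = MEAN_TERMS) {
  stopifnot(inherits(cohort, "perio_cohort"),
            all(mean_terms %in% MEAN_TERMS))
  si <- site_index()
  K <- n_subjects(cohort)
  ns <- n_sites(cohort)
  ptr <- c(0L, cumsum(ns))
  rows <- unlist(lapply(cohort$teeth, sites_of_teeth))  # canonical site ids
  idx <- rep(seq_len(K), ns)
  nteeth <- lengths(cohort$teeth)
  logT <- log(nteeth)

  parts <- list(`(Intercept)` = matrix(1, length(rows), 1,
                                       dimnames = list(NULL, "(Intercept)")))
  blk <- site_design_block()
  if ("site_type" %in% mean_terms)
    parts$site <- blk[rows, 1:5, drop = FALSE]
  if ("sextant" %in% mean_terms)
    parts$sextant <- blk[rows, 6:10, drop = FALSE]
  if ("log_teeth" %in% mean_terms)
    parts$log_teeth <- matrix(logT[idx], ncol = 1,
                              dimnames = list(NULL, "log_teeth"))
  if ("age" %in% mean_terms) {
    ag <- factor(cohort$subjects$age_group, levels = PERIO_AGE_GROUPS)
    am <- stats::model.matrix(~ ag)[, -1, drop = FALSE]
    colnames(am) <- paste0("age_", PERIO_AGE_GROUPS[-1])
    parts$age <- am[idx, , drop = FALSE]
  }
  X <- do.call(cbind, unname(parts))

  structure(list(
    X = X, ptr = ptr, cluster = idx,
    site_id = rows,
    y = unlist(cohort$status),
    miss = unlist(cohort$miss),
    tooth = si$tooth[rows],
    ip = ifelse(is.na(si$ip_space[rows]), 0L, si$ip_space[rows]),
    jaw = as.integer(si$jaw[rows]) - 1L,
    opp = si$opposing_tooth[rows],
    logT = logT, w = cohort$subjects$weight,
    mean_terms = mean_terms
  ), class = "perio_designs")
}

#' Fit the joint mean/correlation imputation model by paired GEE
#'
#' Estimates the marginal mean model (logistic regression for the
#' probability that a site meets the disease threshold) and the
#' within-mouth pairwise correlation model (linear in site-pair category
#' indicators and the log number of teeth) simultaneously by paired
#' estimating equations: Fisher-scoring steps for the mean coefficients
#' with a working covariance assembled from the current correlation model,
#' alternating with a closed-form weighted least-squares step that
#' regresses the standardized residual cross-products
#' \eqn{Z_{ijk} = (Y_{ij}-\mu_{ij})(Y_{ik}-\mu_{ik})/\sqrt{v_{ij} v_{ik}}}
#' on the pair design under working independence across pairs
#' (Prentice-style second-order equations, no third/fourth-moment
#' weighting).  The joint covariance of \eqn{\hat\theta = (\hat\beta,
#' \hat\alpha)} is the empirical sandwich over clusters, including the
#' cross-derivative of the correlation equations with respect to the mean
#' coefficients.  Cluster sampling weights multiply both equations'
#' contributions.
#'
#' @param cohort a `perio_cohort` (masked or full); only observed 0/1 sites
#'   enter the fit.
#' @param mean_terms covariate groups of the mean model (see
#'   [build_designs()]); intercept always included.
#' @param corr_terms correlation-model terms among
#'   `c("same_tooth", "adjacent_same_ip", "adjacent_diff_ip", "opposing",
#'   "log_teeth")`; the intercept (reference: different-teeth,
#'   non-adjacent pairs) is always included.
#' @param fit_alpha if `FALSE`, the correlation model is fixed at zero
#'   (working independence) and only the mean model is fitted.
#' @param control list: `tol` (max absolute coefficient update, default
#'   1e-6), `maxit` (max alternations, 50), `rho_max` (fitted correlations
#'   are clamped into `(-rho_max, rho_max)` inside the working covariance,
#'   0.99), `eig_floor` (eigenvalue floor of the nearest-positive-definite
#'   adjustment used when a cluster's working covariance is not positive
#'   definite, 1e-6).
#' @return object of class `perio_gee` with elements `beta`, `alpha`,
#'   `theta`, `vcov` (joint), `converged`, `iterations`, `max_delta`, and
#'   bookkeeping needed to rebuild per-mouth means and correlations.
#' @export
fit_gee <- function(cohort, mean_terms = MEAN_TERMS,
                    corr_terms = CORR_TERMS, fit_alpha = TRUE,
                    control = list()) {
  ctl <- modifyList(list(tol = 1e-6, maxit = 50L, rho_max = 0.99,
                         eig_floor = 1e-6), control)
  d <- build_designs(cohort, mean_terms = mean_terms)
  obs <- d$miss == MISS_OBSERVED
  if (!any(obs)) stop("no observed sites to fit")
  nobs_cluster <- tabulate(d$cluster[obs], nbins = n_subjects(cohort))
  if (any(nobs_cluster == 0L))
    stop("cluster(s) with no observed sites cannot enter the fit: ",
         paste(utils::head(cohort$subjects$subject_id[nobs_cluster == 0L],
                           5L), collapse = ", "))
  if (any(nobs_cluster == 1L))
    warning(sum(nobs_cluster == 1L),
            " mouth(s) with a single observed site contribute no pairs")
  X <- d$X[obs, , drop = FALSE]
  if (qr(X)$rank < ncol(X))
    stop("mean design is rank deficient on the observed sites; drop terms ",
         "or pool categories")
  ptr <- c(0L, cumsum(nobs_cluster))
  stopifnot(all(corr_terms %in% CORR_TERMS))
  corr_cols <- c(0L, match(corr_terms, CORR_TERMS))
  alpha0 <- rep(0, length(corr_cols))

  res <- gee_engine(
    y = d$y[obs], X = X, ptr = as.integer(ptr), w = d$w,
    tooth = d$tooth[obs], ip = d$ip[obs], jaw = d$jaw[obs],
    opp = d$opp[obs], logT = d$logT,
    corr_cols = as.integer(corr_cols), fit_alpha = fit_alpha,
    beta = rep(0, ncol(X)), alpha = alpha0,
    tol = ctl$tol, maxit = as.integer(ctl$maxit),
    rho_max = ctl$rho_max, eig_floor = ctl$eig_floor)

  if (res$max_abs_eta > 30)
    stop("apparent separation in the mean model (|linear predictor| > 30)")
  if (!res$converged)
    stop("paired GEE did not converge in ", ctl$maxit,
         " alternations (last max coefficient update ",
         signif(res$max_delta, 4), ")")

  beta <- as.numeric(res$beta); names(beta) <- colnames(X)
  anames <- c("(Intercept)", corr_terms)
  alpha <- as.numeric(res$alpha)
  names(alpha) <- if (fit_alpha) anames else anames[seq_along(alpha)]
  vcov <- res$vcov
  thnames <- if (fit_alpha) c(names(beta), paste0("corr:", anames))
             else names(beta)
  dimnames(vcov) <- list(thnames, thnames)
  structure(list(
    beta = beta, alpha = alpha,
    theta = if (fit_alpha) c(beta, stats::setNames(alpha,
                                                   paste0("corr:", anames)))
            else beta,
    vcov = vcov, fit_alpha = fit_alpha,
    converged = res$converged, iterations = res$iterations,
    max_delta = res$max_delta,
    mean_terms = mean_terms, corr_terms = corr_terms,
    corr_cols = corr_cols,
    n_clusters = n_subjects(cohort), n_obs_sites = sum(obs)
  ), class = "perio_gee")
}

#' @export
print.perio_gee <- function(x, ...) {
  cat("Paired GEE fit: ", x$n_clusters, " mouths, ", x$n_obs_sites,
      " observed sites; converged in ", x$iterations, " alternations\n",
      sep = "")
  cat("Mean model (logit):\n")
  print(round(x$beta, 4))
  if (x$fit_alpha) {
    cat("Correlation model:\n")
    print(round(x$alpha, 4))
  } else cat("Correlation model fixed at zero (working independence)\n")
  invisible(x)
}

# per-cluster marginal means under a parameter vector theta (beta part) and
# per-cluster category correlations under the alpha part
theta_split <- function(fit, theta) {
  p <- length(fit$beta)
  list(beta = theta[seq_len(p)], alpha = theta[-seq_len(p)])
}

# the five pair-category correlations (reference, same tooth, adjacent same
# IP, adjacent different IP, opposing) for a cluster with log-teeth lT
rho_by_cat <- function(alpha, corr_cols, lT, rho_max = 0.99) {
  rho <- numeric(5)
  for (t in seq_along(corr_cols)) {
    cc <- corr_cols[t]
    if (cc == 0L) rho <- rho + alpha[t]
    else if (cc == 5L) rho <- rho + alpha[t] * lT
    else rho[cc + 1L] <- rho[cc + 1L] + alpha[t]
  }
  # rho[1] is the reference (different-teeth) correlation; entries 2..5 are
  # the same-tooth / adjacent-IP / adjacent-non-IP / opposing categories
  pmin(pmax(rho, -rho_max), rho_max)
}
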