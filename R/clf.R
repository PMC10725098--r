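#' Conditional linear family specification
#'
#' The conditional linear family (CLF) is a joint distribution for a vector
#' of correlated binary variables with given marginal means `mu` and
#' pairwise correlation matrix `R`: variables are generated sequentially,
#' the conditional mean of each being linear in the preceding outcomes,
#'
#' \deqn{\lambda_j = \mu_j + \Sigma_{j,1:j-1} \Sigma_{1:j-1,1:j-1}^{-1}
#'   (y_{1:j-1} - \mu_{1:j-1}),}
#'
#' where \eqn{\Sigma} is the covariance implied by `(mu, R)` with binary
#' variances \eqn{\mu(1-\mu)}.  Conditional means falling outside
#' `[eps, 1-eps]` are clamped before sampling (the feasibility repair for
#' infeasible values).  The element order of `mu`/`R` *is* the conditioning
#' order; when imputing, observed sites come first.
#'
#' @param mu numeric vector of marginal means; values are clamped into
#'   `(eps, 1-eps)`.
#' @param R correlation matrix (symmetric, unit diagonal) of the same
#'   dimension.
#' @param eps clamping tolerance (default 1e-6).
#' @return object of class `clf_spec`.
#' @export
clf_spec <- function(mu, R, eps = 1e-6) {
  n <- length(mu)
  R <- as.matrix(R)
  stopifnot(n >= 1, nrow(R) == n, ncol(R) == n)
  if (max(abs(R - t(R))) > 1e-8) stop("R must be symmetric")
  if (max(abs(diag(R) - 1)) > 1e-8) stop("R must have unit diagonal")
  if (any(!is.finite(mu)) || any(mu <= 0 - eps) || any(mu >= 1 + eps))
    stopifnot(all(is.finite(mu)))
  mu <- pmin(pmax(mu, eps), 1 - eps)
  structure(list(mu = as.numeric(mu), R = R, eps = eps, n = n),
            class = "clf_spec")
}

clf_sigma <- function(spec) {
  v <- spec$mu * (1 - spec$mu)
  s <- sqrt(v)
  Sigma <- spec$R * tcrossprod(s)
  diag(Sigma) <- v
  Sigma
}

# regression coefficients of variable j on variables 1..j-1 implied by the
# covariance (the linear conditional-mean weights); ridge repair on a
# singular leading block
clf_coef <- function(Sigma, j, ridge = 1e-8) {
  if (j == 1L) return(numeric(0))
  blk <- Sigma[seq_len(j - 1L), seq_len(j - 1L), drop = FALSE]
  cross <- Sigma[j, seq_len(j - 1L)]
  out <- tryCatch(solve(blk, cross), error = function(e) NULL)
  if (is.null(out)) {
    blk2 <- blk + diag(ridge, j - 1L)
    out <- tryCatch(solve(blk2, cross), error = function(e) NULL)
    if (is.null(out))
      stop("singular leading covariance block in CLF conditional mean ",
           "(position ", j, "), even after ridge")
  }
  out
}

#' CLF conditional mean
#'
#' The conditional probability that variable `j` equals 1 given the
#' realized history of variables `1..j-1` in the conditioning order,
#' clamped into `[eps, 1-eps]`.
#'
#' @param spec a [clf_spec()].
#' @param j position in the conditioning order (1-based).
#' @param history binary vector of length `j-1` of realized values.
#' @return a probability.
#' @examples
#' s <- clf_spec(c(0.5, 0.5), matrix(c(1, .5, .5, 1), 2))
#' clf_conditional_mean(s, 2, 1)  # 0.75
#' @export
clf_conditional_mean <- function(spec, j, history = numeric(0)) {
  stopifnot(inherits(spec, "clf_spec"), j >= 1, j <= spec$n,
            length(history) == j - 1)
  Sigma <- clf_sigma(spec)
  cf <- clf_coef(Sigma, j)
  lam <- spec$mu[j] +
    if (j > 1L) sum(cf * (history - spec$mu[seq_len(j - 1L)])) else 0
  min(max(lam, spec$eps), 1 - spec$eps)
}

#' Draw correlated binary vectors from a CLF specification
#'
#' Sequential sampling: each variable is drawn Bernoulli with the CLF
#' conditional mean given all preceding variables.  A partial assignment
#' can be fixed, provided the fixed entries occupy a prefix of the
#' conditioning order (the imputation use case: observed sites first).
#' One covariance factorization is shared by all draws.
#'
#' @param spec a [clf_spec()].
#' @param fixed optional vector of length `n`: 0/1 for fixed entries, NA
#'   for entries to draw.  Non-NA entries must form a prefix.
#' @param ndraws number of vectors to draw.
#' @param seed optional integer seed.
#' @return for `ndraws = 1` an integer vector, otherwise an
#'   `ndraws x n` matrix; attribute `clamp_rate` gives the fraction of
#'   drawn conditionals that required clamping.
#' @export
clf_sample <- function(spec, fixed = NULL, ndraws = 1L, seed = NULL) {
  stopifnot(inherits(spec, "clf_spec"))
  n <- spec$n
  if (is.null(fixed)) fixed <- rep(NA_integer_, n)
  stopifnot(length(fixed) == n)
  fx <- as.integer(fixed)
  k <- sum(!is.na(fx))
  if (k > 0 && any(is.na(fx[seq_len(k)])))
    stop("fixed entries must occupy a prefix of the conditioning order")
  if (any(!is.na(fx) & !fx %in% 0:1)) stop("fixed entries must be 0/1")
  fx[is.na(fx)] <- -1L
  res <- with_seed(seed,
                   clf_draw_sigma_engine(spec$mu, spec$R, fx, spec$eps,
                                         1e-8, FALSE, as.integer(ndraws)))
  if (!isTRUE(res$ok))
    stop("CLF covariance is singular (not positive definite even after ",
         "ridge); check that (mu, R) is a feasible specification")
  Y <- res$y
  out <- if (ndraws == 1L) as.integer(Y[1L, ]) else {
    storage.mode(Y) <- "integer"
    Y
  }
  attr(out, "clamp_rate") <- if (res$n_drawn > 0)
    res$n_clamped / res$n_drawn else 0
  out
}

#' Exact CLF probability mass function by enumeration
#'
#' Enumerates all `2^n` outcomes and multiplies the sequential conditional
#' probabilities (with the same clamping rule the sampler uses).  Intended
#' as a small-`n` oracle for the sampler and for moment checks; the
#' conditional means are computed from the direct linear-solve formula, a
#' separate code path from the sampler's incremental factorization.
#'
#' @param spec a [clf_spec()] with `n <= 12`.
#' @return data.frame with the `2^n` outcomes (matrix column `y`) and their
#'   probabilities (`prob`); probabilities sum to 1.
#' @export
clf_exact_pmf <- function(spec) {
  stopifnot(inherits(spec, "clf_spec"))
  n <- spec$n
  if (n > 12L) stop("exact enumeration is limited to n <= 12")
  Sigma <- clf_sigma(spec)
  coefs <- lapply(seq_len(n), function(j) clf_coef(Sigma, j))
  grid <- as.matrix(expand.grid(rep(list(0:1), n)))
  colnames(grid) <- NULL
  prob <- rep(1, nrow(grid))
  for (j in seq_len(n)) {
    if (j == 1L) {
      lam <- rep(spec$mu[1L], nrow(grid))
    } else {
      dev <- sweep(grid[, seq_len(j - 1L), drop = FALSE], 2L,
                   spec$mu[seq_len(j - 1L)])
      lam <- spec$mu[j] + as.numeric(dev %*% coefs[[j]])
    }
    lam <- pmin(pmax(lam, spec$eps), 1 - spec$eps)
    prob <- prob * ifelse(grid[, j] == 1L, lam, 1 - lam)
  }
  data.frame(y = I(grid), prob = prob)
}

# first and second moments of an enumerated pmf (test utility)
clf_pmf_moments <- function(pmf) {
  Y <- unclass(pmf$y)
  p <- pmf$prob
  mu <- as.numeric(crossprod(Y, p))
  EYY <- crossprod(Y, Y * p)
  Cov <- EYY - tcrossprod(mu)
  s <- sqrt(diag(Cov))
  list(mu = mu, R = Cov / tcrossprod(s))
}
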