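# Deterministic substream seed derived from a master seed and indices, so
# per-subject draws do not depend on cohort order or on draws made for
# other subjects.  Kept below 2^31 - 1.
substream_seed <- function(master, ...) {
  idx <- c(...)
  s <- as.double(master) %% 2147483647
  for (k in idx) {
    s <- (s * 48271 + as.double(k) * 9349 + 1) %% 2147483647
  }
  as.integer(s)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Mask a full-mouth cohort with a random site selection protocol
#'
#' Applies a random site selection method (RSSM): for each mouth,
#' `min(m, n_i)` of the `n_i` existing tooth sites are kept by simple random
#' sampling without replacement, independently across subjects; all other
#' existing sites become missing-nonselected.  Sites unmeasured for
#' technical reasons are eligible for selection (they stay
#' technical-missing if selected) — both kinds of missing site are later
#' imputed.  Selection uses a per-subject random substream derived from
#' `seed` and the subject's position, so a fixed seed gives a reproducible
#' mask.
#'
#' @param cohort a full-mouth `perio_cohort` (no nonselected sites yet).
#' @param m target number of sites per mouth (the designs studied here use
#'   28, 36, 42 or 84; any value in 1-168 is accepted).
#' @param seed integer master seed.
#' @return masked `perio_cohort`.
#' @export
apply_rssm <- function(cohort, m, seed = NULL) {
  stopifnot(inherits(cohort, "perio_cohort"))
  if (length(m) != 1L || !is.finite(m) || m < 1 || m > 168)
    stop("m must be a single integer in 1..168")
  m <- as.integer(m)
  if (any(unlist(cohort$miss) == MISS_NONSELECTED))
    stop("cohort already carries nonselected sites; apply_rssm expects a ",
         "full-mouth cohort")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  K <- n_subjects(cohort)
  ns <- n_sites(cohort)
  for (i in seq_len(K)) {
    ni <- ns[i]
    mi <- min(m, ni)
    if (mi == ni) next
    keep <- with_seed(substream_seed(seed, 1L, i),
                      sample.int(ni, mi, replace = FALSE))
    drop <- setdiff(seq_len(ni), keep)
    cohort$status[[i]][drop] <- NA_integer_
    cohort$miss[[i]][drop] <- MISS_NONSELECTED
  }
  cohort
}

#' Resample clusters with replacement
#'
#' Draws `size` mouths with replacement from a cohort; duplicated mouths are
#' retained as independent clusters (the evaluation harness and the
#' bootstrap both build on this).
#'
#' @param cohort a `perio_cohort`.
#' @param size number of clusters to draw (default: the cohort size).
#' @param seed integer seed (optional).
#' @return resampled `perio_cohort`.
#' @export
resample_clusters <- function(cohort, size = NULL, seed = NULL) {
  stopifnot(inherits(cohort, "perio_cohort"))
  K <- n_subjects(cohort)
  if (K < 1L) stop("cannot resample an empty cohort")
  if (is.null(size)) size <- K
  stopifnot(size >= 1)
  idx <- with_seed(seed, sample.int(K, size, replace = TRUE))
  subset_cohort(cohort, idx)
}

# index a cohort by cluster positions (repeats allowed)
subset_cohort <- function(cohort, idx) {
  structure(list(subjects = cohort$subjects[idx, , drop = FALSE],
                 teeth = cohort$teeth[idx],
                 status = cohort$status[idx],
                 miss = cohort$miss[idx],
                 threshold = cohort$threshold),
            class = "perio_cohort")
}
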