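#' Threshold a clinical attachment loss measurement
#'
#' Converts a CAL measurement in millimetres into the binary indicator of
#' meeting or exceeding a fixed threshold (closed threshold: `CAL3+` means
#' CAL of 3 mm or greater).
#'
#' @param cal_mm numeric vector of nonnegative CAL measurements in mm;
#'   `NA` is passed through (missing for technical reasons).
#' @param threshold_mm positive threshold in mm (default 3).
#' @return integer vector of 0/1 indicators (NA preserved).
#' @examples
#' threshold_cal(c(0, 2.9, 3, 5.5))  # 0 0 1 1
#' @export
threshold_cal <- function(cal_mm, threshold_mm = 3) {
  stopifnot(is.numeric(cal_mm), length(threshold_mm) == 1L,
            is.finite(threshold_mm), threshold_mm > 0)
  if (any(cal_mm < 0, na.rm = TRUE))
    stop("negative CAL measurement: CAL must be nonnegative mm")
  as.integer(cal_mm >= threshold_mm)
}

#' Construct a periodontal cohort
#'
#' A `perio_cohort` holds one record per mouth (cluster): the subject's
#' sampling weight, age group, set of present non-third-molar teeth, and a
#' 0/1 disease status for every site of every present tooth, together with a
#' missingness code distinguishing sites unmeasured for technical reasons
#' from sites not selected by a partial-mouth protocol.  Sites of absent
#' teeth are structurally nonexistent and carry no status.  Subject ids need
#' not be unique: with-replacement cluster resamples keep duplicates as
#' distinct clusters.
#'
#' @param subjects data frame with columns `subject_id`, `weight` (positive),
#'   `age_group` (one of `r paste(PERIO_AGE_GROUPS, collapse = ", ")`).
#' @param teeth list (one element per subject) of integer vectors of present
#'   teeth, universal numbering 2-15 and 18-31.
#' @param status list of integer vectors, one entry per site of each present
#'   tooth in canonical order (tooth ascending, site type in fixed order);
#'   0/1, or NA where the matching `miss` code is nonzero.
#' @param miss list of integer vectors: 0 observed, 1 missing for technical
#'   reasons, 2 not selected by the recording protocol.  Defaults to all
#'   observed where `status` is non-NA, technical where NA.
#' @param threshold character label for the site indicator (provenance only).
#' @return object of class `perio_cohort`.
#' @export
perio_cohort <- function(subjects, teeth, status, miss = NULL,
                         threshold = "CAL3+") {
  stopifnot(is.data.frame(subjects),
            all(c("subject_id", "weight", "age_group") %in% names(subjects)))
  K <- nrow(subjects)
  stopifnot(length(teeth) == K, length(status) == K)
  if (is.null(miss)) {
    miss <- lapply(status, function(s) ifelse(is.na(s), MISS_TECHNICAL,
                                              MISS_OBSERVED))
  }
  stopifnot(length(miss) == K)
  subjects$subject_id <- as.character(subjects$subject_id)
  subjects$age_group <- as.character(subjects$age_group)
  bad_age <- !subjects$age_group %in% PERIO_AGE_GROUPS
  if (any(bad_age))
    stop("unknown age_group for subject(s): ",
         paste(utils::head(subjects$subject_id[bad_age], 5L), collapse = ", "))
  if (any(!is.finite(subjects$weight)) || any(subjects$weight <= 0))
    stop("weights must be positive and finite")
  for (i in seq_len(K)) {
    ti <- teeth[[i]]
    if (length(ti) < 1L)
      stop("subject ", subjects$subject_id[i], " has no teeth present")
    if (anyDuplicated(ti))
      stop("subject ", subjects$subject_id[i], " has duplicated teeth")
    if (!all(ti %in% PERIO_TEETH))
      stop("subject ", subjects$subject_id[i],
           " has tooth outside the 28-tooth universe (third molars excluded): ",
           paste(setdiff(ti, PERIO_TEETH), collapse = ", "))
    teeth[[i]] <- sort(as.integer(ti))
    ni <- 6L * length(ti)
    si <- as.integer(status[[i]]); mi <- as.integer(miss[[i]])
    if (length(si) != ni || length(mi) != ni)
      stop("subject ", subjects$subject_id[i], ": expected ", ni,
           " site statuses (6 per present tooth), got ", length(si))
    if (any(!is.na(si) & !si %in% 0:1))
      stop("subject ", subjects$subject_id[i], ": statuses must be 0/1/NA")
    if (any(is.na(si) != (mi > 0L)))
      stop("subject ", subjects$subject_id[i],
           ": NA status must coincide with a nonzero missingness code")
    status[[i]] <- si; miss[[i]] <- mi
  }
  structure(list(subjects = subjects, teeth = teeth, status = status,
                 miss = miss, threshold = threshold),
            class = "perio_cohort")
}

#' @export
print.perio_cohort <- function(x, ...) {
  K <- nrow(x$subjects)
  n_sites <- sum(lengths(x$status))
  n_tech <- sum(vapply(x$miss, function(m) sum(m == MISS_TECHNICAL), 0L))
  n_mask <- sum(vapply(x$miss, function(m) sum(m == MISS_NONSELECTED), 0L))
  cat("perio_cohort: ", K, " mouths, ", n_sites, " existing tooth sites (",
      x$threshold, ")\n", sep = "")
  cat("  teeth per mouth: ", paste(range(lengths(x$teeth)), collapse = "-"),
      "; technical-missing sites: ", n_tech,
      "; protocol-masked sites: ", n_mask, "\n", sep = "")
  invisible(x)
}

n_subjects <- function(cohort) nrow(cohort$subjects)

# per-subject number of existing sites n_i = 6 * |teeth|
n_sites <- function(cohort) 6L * lengths(cohort$teeth)

is_complete_cohort <- function(cohort) {
  all(vapply(cohort$status, function(s) !anyNA(s), logical(1L)))
}

#' Convert a cohort to tidy long format
#'
#' One row per existing tooth site, columns `subject_id`, `weight`,
#' `age_group`, `tooth`, `site` (site-type label), `status` (0/1 or NA) and
#' `missing` (`""`, `"technical"` or `"nonselected"`).  Rows for absent
#' teeth are not emitted.
#'
#' @param x a `perio_cohort`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return data.frame in long format.
#' @export
as.data.frame.perio_cohort <- function(x, row.names = NULL,
                                       optional = FALSE, ...) {
  K <- n_subjects(x)
  ns <- n_sites(x)
  idx <- rep(seq_len(K), ns)
  data.frame(
    subject_id = x$subjects$subject_id[idx],
    weight = x$subjects$weight[idx],
    age_group = x$subjects$age_group[idx],
    tooth = unlist(lapply(x$teeth, function(t) rep(t, each = 6L))),
    site = rep(PERIO_SITE_TYPES, length.out = sum(ns)),
    status = unlist(x$status),
    missing = c("", "technical", "nonselected")[unlist(x$miss) + 1L],
    stringsAsFactors = FALSE
  )
}

#' Build a cohort from a long-format table
#'
#' @param df data.frame with columns `subject_id`, `weight`, `age_group`,
#'   `tooth`, `site`, `status`, and optionally `missing`.  One row per
#'   (subject, tooth, site); rows for absent teeth are simply not present.
#'   All six sites of every listed tooth must appear.
#' @param threshold provenance label.
#' @return a `perio_cohort`.
#' @export
cohort_from_long <- function(df, threshold = "CAL3+") {
  req <- c("subject_id", "weight", "age_group", "tooth", "site", "status")
  if (!all(req %in% names(df)))
    stop("long-format table must have columns: ", paste(req, collapse = ", "))
  bad_tooth <- !df$tooth %in% PERIO_TEETH
  if (any(bad_tooth))
    stop("unknown tooth number (third molars are excluded) in row(s): ",
         paste(utils::head(which(bad_tooth), 5L), collapse = ", "))
  bad_site <- !df$site %in% PERIO_SITE_TYPES
  if (any(bad_site))
    stop("unknown site code in row(s): ",
         paste(utils::head(which(bad_site), 5L), collapse = ", "),
         " (expected one of: ", paste(PERIO_SITE_TYPES, collapse = ", "), ")")
  key <- paste(df$subject_id, df$tooth, df$site)
  if (anyDuplicated(key))
    stop("duplicate (subject, tooth, site) at row(s): ",
         paste(utils::head(which(duplicated(key)), 5L), collapse = ", "))
  if (is.null(df$missing)) df$missing <- ifelse(is.na(df$status),
                                                "technical", "")
  df$missing[is.na(df$missing)] <- ""
  bad_miss <- !df$missing %in% c("", "technical", "nonselected")
  if (any(bad_miss))
    stop("unknown missing code in row(s): ",
         paste(utils::head(which(bad_miss), 5L), collapse = ", "))
  if (any(df$missing == "" & is.na(df$status)))
    stop("NA status without a missing code; mark it 'technical' or ",
         "'nonselected'")
  if (any(df$missing != "" & !is.na(df$status)))
    stop("non-NA status flagged as missing")

  sid <- factor(df$subject_id, levels = unique(df$subject_id))
  ord <- order(as.integer(sid), df$tooth,
               match(df$site, PERIO_SITE_TYPES))
  df <- df[ord, ]
  sid <- sid[ord]
  first <- !duplicated(sid)
  subjects <- data.frame(subject_id = as.character(sid[first]),
                         weight = df$weight[first],
                         age_group = as.character(df$age_group[first]),
                         stringsAsFactors = FALSE)
  teeth <- lapply(split(df$tooth, sid), function(t) sort(unique(t)))
  # every listed tooth must carry all 6 sites
  cnt <- tapply(df$tooth, sid, length)
  expect <- 6L * lengths(teeth)
  if (any(cnt != expect)) {
    bad <- names(cnt)[which(cnt != expect)]
    stop("subject(s) with incomplete site rows for a present tooth: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  status <- split(as.integer(df$status), sid)
  miss <- split(match(df$missing, c("", "technical", "nonselected")) - 1L,
                sid)
  perio_cohort(subjects, unname(teeth), unname(status), unname(miss),
               threshold = threshold)
}

#' Read a cohort from delimited text
#'
#' Reads either the tidy long format (one row per subject-tooth-site; see
#' [cohort_from_long()]) or, when a `mapping` is supplied, a wide one-row-
#' per-subject table with per-tooth-site CAL columns (e.g. derived from an
#' NHANES SAS transport file), thresholded on read.
#'
#' @param path file path of a delimited text file with a header row.
#' @param mapping `NULL` for the long format, or a column-mapping list (or
#'   path to a YAML file) for wide tables with fields: `subject_id`
#'   (column name); `weight` (column name, optional, default weight 1);
#'   `age` (column of age in years) or `age_group` (column of group labels);
#'   `cal_template` (e.g. `"CAL_{tooth}_{code}"`, `{tooth}` is the
#'   zero-padded 2-digit universal number, `{code}` a site code); optional
#'   `site_codes` named list mapping the six site-type labels to the codes
#'   used in column names (default DB, B, MB, ML, L, DL); optional
#'   `threshold_mm` (default 3).  A tooth is present when at least one of
#'   its six CAL columns is non-missing; missing cells of present teeth
#'   become technical missingness.
#' @param sep field separator (default `","`).
#' @param threshold provenance label for long-format reads.
#' @return a `perio_cohort`.
#' @export
read_cohort <- function(path, mapping = NULL, sep = ",",
                        threshold = "CAL3+") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (is.null(mapping)) return(cohort_from_long(df, threshold = threshold))
  if (is.character(mapping) && length(mapping) == 1L)
    mapping <- yaml::read_yaml(mapping)
  cohort_from_wide(df, mapping)
}

default_site_codes <- c("distal-buccal" = "DB", "buccal" = "B",
                        "mesio-buccal" = "MB", "mesio-lingual" = "ML",
                        "lingual" = "L", "disto-lingual" = "DL")

cohort_from_wide <- function(df, mapping) {
  stopifnot(!is.null(mapping$subject_id), !is.null(mapping$cal_template))
  codes <- default_site_codes
  if (!is.null(mapping$site_codes)) {
    sc <- unlist(mapping$site_codes)
    stopifnot(all(names(sc) %in% PERIO_SITE_TYPES))
    codes[names(sc)] <- sc
  }
  thr <- if (is.null(mapping$threshold_mm)) 3 else mapping$threshold_mm
  col_of <- function(tooth, stype) {
    nm <- gsub("{tooth}", sprintf("%02d", tooth), mapping$cal_template,
               fixed = TRUE)
    gsub("{code}", codes[[stype]], nm, fixed = TRUE)
  }
  sid <- as.character(df[[mapping$subject_id]])
  weight <- if (is.null(mapping$weight)) rep(1, nrow(df))
            else as.numeric(df[[mapping$weight]])
  if (!is.null(mapping$age_group)) {
    age_group <- as.character(df[[mapping$age_group]])
  } else if (!is.null(mapping$age)) {
    yrs <- as.numeric(df[[mapping$age]])
    if (any(yrs < 30, na.rm = TRUE))
      stop("age under 30 years is outside the supported age groups; ",
           "pre-filter the table")
    age_group <- as.character(cut(yrs, c(30, 40, 50, 60, 70, Inf),
                                  labels = PERIO_AGE_GROUPS, right = FALSE))
  } else stop("mapping must provide 'age' or 'age_group'")

  cal <- array(NA_real_, dim = c(nrow(df), 28L, 6L))
  for (ti in seq_along(PERIO_TEETH)) for (si in 1:6) {
    cn <- col_of(PERIO_TEETH[ti], PERIO_SITE_TYPES[si])
    if (!cn %in% names(df))
      stop("mapped CAL column not found in table: ", cn)
    cal[, ti, si] <- as.numeric(df[[cn]])
  }
  teeth <- vector("list", nrow(df)); status <- teeth; miss <- teeth
  for (i in seq_len(nrow(df))) {
    present <- which(apply(!is.na(cal[i, , , drop = TRUE]), 1L, any))
    if (length(present) == 0L)
      stop("subject ", sid[i], " has no teeth with any CAL measurement")
    teeth[[i]] <- PERIO_TEETH[present]
    v <- as.numeric(t(cal[i, present, , drop = TRUE]))
    status[[i]] <- threshold_cal(v, thr)
    miss[[i]] <- ifelse(is.na(v), MISS_TECHNICAL, MISS_OBSERVED)
  }
  perio_cohort(data.frame(subject_id = sid, weight = weight,
                          age_group = age_group, stringsAsFactors = FALSE),
               teeth, status, miss,
               threshold = sprintf("CAL%g+", thr))
}

#' Write a cohort as tidy long-format delimited text
#'
#' Inverse of the long-format [read_cohort()]; a write-then-read round trip
#' reproduces every site status and missingness code exactly.
#'
#' @param cohort a `perio_cohort`.
#' @param path output file path.
#' @param sep field separator (default `","`).
#' @export
write_cohort <- function(cohort, path, sep = ",") {
  if (anyDuplicated(cohort$subjects$subject_id)) {
    # resampled cohorts keep duplicate clusters; disambiguate ids on disk
    cohort$subjects$subject_id <- make.unique(cohort$subjects$subject_id,
                                              sep = "#")
  }
  df <- as.data.frame(cohort)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = TRUE)
  invisible(path)
}
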