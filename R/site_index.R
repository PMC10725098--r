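#' @useDynLib periomi, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats plogis qlogis rbinom rgamma rnorm runif var
#' @importFrom utils read.table write.table modifyList head
NULL

# Universal tooth numbering, third molars (1, 16, 17, 32) excluded.
PERIO_TEETH <- c(2:15, 18:31)

# Six probing sites per tooth in fixed canonical order.
PERIO_SITE_TYPES <- c("distal-buccal", "buccal", "mesio-buccal",
                      "mesio-lingual", "lingual", "disto-lingual")

PERIO_AGE_GROUPS <- c("30-39", "40-49", "50-59", "60-69", "70+")

PERIO_SEXTANTS <- c("maxillary right posterior", "maxillary anterior",
                    "maxillary left posterior", "mandibular left posterior",
                    "mandibular anterior", "mandibular right posterior")

# Missingness codes carried alongside 0/1 site statuses.
MISS_OBSERVED    <- 0L
MISS_TECHNICAL   <- 1L
MISS_NONSELECTED <- 2L

sextant_of_tooth <- function(tooth) {
  out <- character(length(tooth))
  out[tooth >= 2 & tooth <= 5]   <- "maxillary right posterior"
  out[tooth >= 6 & tooth <= 11]  <- "maxillary anterior"
  out[tooth >= 12 & tooth <= 15] <- "maxillary left posterior"
  out[tooth >= 18 & tooth <= 21] <- "mandibular left posterior"
  out[tooth >= 22 & tooth <= 27] <- "mandibular anterior"
  out[tooth >= 28 & tooth <= 31] <- "mandibular right posterior"
  out
}

jaw_of_tooth <- function(tooth) {
  ifelse(tooth <= 15, "maxillary", "mandibular")
}

#' Tooth directly above/below on the opposite jaw
#'
#' In universal numbering (third molars excluded) the maxillary tooth `t`
#' opposes mandibular tooth `33 - t`: 2 opposes 31, 8 opposes 25, and so on.
#'
#' @param tooth integer vector of universal tooth numbers (2-15, 18-31).
#' @return integer vector of opposing tooth numbers.
#' @export
opposing_tooth <- function(tooth) {
  stopifnot(all(tooth %in% PERIO_TEETH))
  33L - as.integer(tooth)
}

# Interproximal space id faced by each (tooth, site) pair, or NA for the
# mid (buccal/lingual) sites.  A space is labelled by the smaller universal
# number of the two teeth flanking it; spaces next to excluded third molars
# do not exist.  Mesial surfaces point toward the midline (between teeth
# 8|9 above and 24|25 below), so the tooth-to-space map flips direction at
# the midline.
ip_space_of <- function(tooth, site_type) {
  tooth <- as.integer(tooth)
  side <- rep(NA_character_, length(site_type))
  side[site_type %in% c("mesio-buccal", "mesio-lingual")] <- "mesial"
  side[site_type %in% c("distal-buccal", "disto-lingual")] <- "distal"
  out <- rep(NA_integer_, length(tooth))
  mesial <- !is.na(side) & side == "mesial"
  distal <- !is.na(side) & side == "distal"
  pre_mid <- (tooth >= 2 & tooth <= 8) | (tooth >= 18 & tooth <= 24)
  # tooth numbers increase toward the midline before it, away after it
  out[mesial & pre_mid]  <- tooth[mesial & pre_mid]
  out[mesial & !pre_mid] <- tooth[mesial & !pre_mid] - 1L
  out[distal & pre_mid]  <- tooth[distal & pre_mid] - 1L
  out[distal & !pre_mid] <- tooth[distal & !pre_mid]
  # no IP space beyond the terminal (second molar) tooth of each arch
  out[!is.na(out) & out %in% c(1L, 15L, 17L, 31L)] <- NA_integer_
  out
}

#' Canonical index of the 168 non-third-molar tooth sites
#'
#' Enumerates all `28 teeth x 6 sites = 168` periodontal probing sites in the
#' fixed canonical order (tooth ascending, site type in the order
#' distal-buccal, buccal, mesio-buccal, mesio-lingual, lingual,
#' disto-lingual), with sextant, jaw, interproximal-space and opposing-tooth
#' attributes used by the correlation model.
#'
#' @return A data frame with one row per site and columns `site_id` (1-168),
#'   `tooth`, `site_type`, `sextant`, `jaw`, `ip_space` (NA for buccal and
#'   lingual mid sites), and `opposing_tooth`.
#' @examples
#' si <- site_index()
#' nrow(si)           # 168
#' table(si$sextant)  # 6 sextants
#' @export
site_index <- function() {
  if (!is.null(.periomi_env$site_index)) return(.periomi_env$site_index)
  tooth <- rep(PERIO_TEETH, each = 6L)
  stype <- factor(rep(PERIO_SITE_TYPES, times = 28L),
                  levels = PERIO_SITE_TYPES)
  si <- data.frame(
    site_id = seq_len(168L),
    tooth = tooth,
    site_type = stype,
    sextant = factor(sextant_of_tooth(tooth), levels = PERIO_SEXTANTS),
    jaw = factor(jaw_of_tooth(tooth), levels = c("maxillary", "mandibular")),
    ip_space = ip_space_of(tooth, as.character(stype)),
    opposing_tooth = opposing_tooth(tooth),
    stringsAsFactors = FALSE
  )
  .periomi_env$site_index <- si
  si
}

.periomi_env <- new.env(parent = emptyenv())

# site ids (1..168) of all six sites of the given teeth, in canonical order
sites_of_teeth <- function(teeth) {
  teeth <- sort(as.integer(teeth))
  pos <- match(teeth, PERIO_TEETH)
  as.integer(outer(1:6, (pos - 1L) * 6L, `+`))
}
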