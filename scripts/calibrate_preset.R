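#!/usr/bin/env Rscript
# One-off calibration of the NHANES-like population preset.
#
# The site-type, sextant, log-teeth and age coefficients, the tooth-count
# and age distributions, and the relative ordering of the correlation
# categories were chosen a priori on subject-matter grounds.  This script
# then measured the full-mouth mean extent and prevalences at K = 3621 for
# a small grid of (intercept, correlation level) pairs and the pair
# landing nearest mean extent ~19 sites and prevalence(h = 1) ~0.9 was
# frozen into nhanes_like_preset():
#
#   intercept 0.22, alpha = (0.28, 0.24, 0.16, 0.07, 0.03, -0.03)
#   -> extent 19.24, prev1 0.891, prev2 0.815 at seed 20260101.
#
# Re-running reproduces the frozen calibration numbers.
suppressPackageStartupMessages(library(periomi))

spec <- nhanes_like_preset()
for (s in c(20260101, 7, 99)) {
  co <- generate_cohort(spec, K = 3621, seed = s)
  # technical-missing sites (<1%) count as unaffected, as in a direct
  # full-mouth calculation
  cat(sprintf(
    "seed %d: extent %.2f  prev1 %.3f  prev2 %.3f\n", s,
    standard_partial_estimate(co, estimand("extent")),
    standard_partial_estimate(co, estimand("prevalence", 1)),
    standard_partial_estimate(co, estimand("prevalence", 2))))
}
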