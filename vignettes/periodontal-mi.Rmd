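---
title: "Multiple imputation for partial-mouth periodontal recording"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiple imputation for partial-mouth periodontal recording}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(periomi)
```

## The problem

A full-mouth periodontal examination (FMPE) probes six sites on each of up
to 28 non-third-molar teeth — at most 168 sites per mouth — and is the gold
standard for surveillance of periodontitis. Because an FMPE is slow and
costly, surveys have long used partial recording protocols that measure
only a subset of sites. The usual analysis applies the full-mouth case
definition directly to the partial data, and this is badly biased: a mouth
with no diseased site can never be misclassified as diseased, but a
diseased mouth can easily have none of its diseased sites selected.
Specificity is 100%, sensitivity is below 100%, so both the *extent* of
disease (the mean number of affected sites per mouth) and its *prevalence*
(the share of mouths with at least `h` affected sites) are systematically
underestimated — historically by tens of percent.

`periomi` implements the alternative: treat the nonselected sites of a
random site selection protocol as data missing completely at random,
multiply impute them from a joint model for correlated binary site
indicators, and estimate extent and prevalence from the pseudo-complete
dentitions.

## Estimands and estimators

Let \(Y_{ij}\) indicate that site \(j\) of mouth \(i\) meets a fixed
threshold (by default clinical attachment loss of 3 mm or more, written
CAL3+, with the closed inequality \(\mathrm{CAL} \ge 3\)). With
\(n_i = 6 \times \#\text{teeth}_i\) existing sites, the subject summary is
\(S_i = \sum_j Y_{ij}\) for extent and \(S_i = I(\sum_j Y_{ij} \ge h)\)
for prevalence. The population estimand is the average of \(S_i\) over
mouths, and the weighted ratio estimator

\[\hat\tau = \frac{\sum_i w_i S_i}{\sum_i w_i}\]

with inverse-selection weights \(w_i\) estimates it from a sample
(`cohort_estimate()`). Its variance uses single-stage with-replacement
Taylor linearization, \(\frac{K}{K-1}\sum_i w_i^2 (S_i -
\hat\tau)^2 / (\sum_i w_i)^2\), which reduces to the classical
\(\sum_i (S_i-\bar S)^2/\{K(K-1)\}\) under equal weights. No survey
strata or PSU structure is modelled; the evaluation treats mouths as iid
clusters.

## The imputation model

The statistical distribution model for a mouth is specified by its first
two moments:

* **Mean model** — a logistic regression for the probability that a site
  is affected, with indicators for the six site types (reference:
  disto-lingual), the six sextants (reference: mandibular right
  posterior), the log number of teeth, and age group (30–39 reference,
  then 40–49, 50–59, 60–69, 70+).
* **Correlation model** — a linear model for the pairwise correlation of
  two sites in the same mouth, with an intercept (reference category:
  sites on different, non-adjacent teeth), indicators for pairs on the
  same tooth, on adjacent teeth facing the same interproximal space, on
  adjacent teeth not sharing that space, and on vertically opposing teeth
  across jaws, plus the log number of teeth.

`fit_gee()` estimates both jointly by paired estimating equations in the
style of Prentice's second-order GEE: Fisher-scoring steps for the mean
coefficients with the working covariance assembled per cluster from the
current correlation model, alternating with a closed-form weighted
least-squares step that regresses the standardized residual cross-products
\(Z_{ijk} = (Y_{ij}-\mu_{ij})(Y_{ik}-\mu_{ik})/\sqrt{v_{ij}v_{ik}}\) on
the pair design under working independence across pairs (no third- or
fourth-moment weighting). The joint covariance of
\(\hat\theta = (\hat\beta, \hat\alpha)\) is the empirical sandwich over
clusters, with the cross-derivative of the correlation equations with
respect to \(\beta\) included in the (block lower-triangular) bread.
Sampling weights multiply both equations' cluster contributions.

Numerical safeguards: fitted correlations are clamped into
\((-0.99, 0.99)\) inside the working covariance; a cluster's working
covariance that is not positive definite is replaced, for the working
inverse only, by its nearest positive-definite adjustment with eigenvalue
floor \(10^{-6}\); convergence requires every coefficient update below
\(10^{-6}\) within 50 alternations, and an apparent separation (|linear
predictor| > 30) is an error rather than a silent divergence.

## Imputation from the conditional linear family

Given \(\hat\theta\) and its covariance, each of the \(M\) imputation
replicates starts from a posterior draw
\(\theta^* \sim \mathrm{MVN}(\hat\theta, V(\hat\theta))\) — one draw per
replicate, shared by all mouths, so that between-imputation variability is
parameter-level. The covariance is projected to positive semi-definite
before factorization (eigenvalues floored at zero); we flag genuinely
negative eigenvalues beyond a *relative* \(10^{-8}\) tolerance, a scale
that matches sandwich matrices whose entries span several orders of
magnitude.

For each mouth, \(\theta^*\) determines marginal means \(\mu_j\) and a
correlation matrix \(R\), and missing sites are drawn sequentially from
the conditional linear family (CLF): the conditional mean of site \(j\)
given the realized history is

\[\lambda_j = \mu_j + \Sigma_{j,1:j-1}\,\Sigma_{1:j-1,1:j-1}^{-1}
  (y_{1:j-1} - \mu_{1:j-1}),\]

with \(\Sigma\) the covariance implied by \((\mu, R)\) and binary
variances \(\mu(1-\mu)\). Observed sites come first in the conditioning
order (their 0/1 values are conditioned on, never altered), followed by
missing sites in canonical order; sites missing for technical reasons
(under 1% in practice) are imputed together with the nonselected ones.
One Cholesky factorization per mouth drives the whole sequential draw.

The CLF does not guarantee that every conditional mean is a probability.
Our feasibility repair clamps \(\lambda_j\) into
\([\varepsilon, 1-\varepsilon]\) with \(\varepsilon = 10^{-6}\) and logs
the clamp rate per replicate (`perio_imputation$clamp_rate`); this is the
simplest repair that preserves sequential sampling, and it is a declared
stand-in for the feasibility modification of the original algorithm,
whose exact form we did not reimplement from its separate publication. A
singular leading covariance block is retried with a ridge of \(10^{-8}\);
inside the imputation engine a non-positive-definite \(\Sigma\) is
additionally repaired by an eigenvalue floor so that a single wild
posterior draw cannot abort a whole replicate. Clamping makes the
realized joint distribution depend mildly on the conditioning order; the
test suite *measures* this deviation on a deliberately strained
specification rather than assuming it away.

`clf_exact_pmf()` enumerates the exact distribution for up to 12 sites
through a separate code path (direct linear solves rather than the
sampler's incremental factorization) and serves as the oracle for the
sampler: outcome frequencies match it in total variation, and when no
clamping occurs its first two moments reproduce \((\mu, R)\) to
\(10^{-10}\).

## Combining: Rubin's rules with bootstrap within-imputation variance

Each completed replicate yields an estimate \(\hat\tau_l\); the MI
estimate is their average, and

\[\hat V = V_W + \left(1 + \tfrac1M\right) V_B,\qquad
  V_B = \frac{\sum_l (\bar\tau - \hat\tau_l)^2}{M-1},\qquad
  V_W = \frac1M \sum_l \hat V_l,\]

where \(\hat V_l\) is the cluster-bootstrap variance of \(\hat\tau_l\)
within replicate \(l\): \(B\) with-replacement resamples of mouths,
sample variance about the bootstrap mean with divisor \(B-1\). This is
the impute-first, bootstrap-within (MI-boot) ordering; bootstrap index
sets are drawn independently per replicate. Defaults are \(M = 25\) and
\(B = 200\), the reference analysis settings; the evaluation harness and
command line expose both.

## Randomness and reproducibility

Every stochastic function takes a master seed and derives substreams from
it: per-subject streams for masking and generation (keyed on subject
position, so reordering a cohort does not silently reshuffle draws),
per-(replicate, subject) streams for imputation, per-replicate streams
for bootstrap and evaluation. A fixed seed therefore reproduces a
masking, an imputation, or an entire evaluation bit for bit, independent
of scheduling.

## The synthetic cohort generator

`generate_cohort()` draws mouths with heterogeneous tooth counts, age
groups, optional gamma-distributed weights and technically missing sites
(default rate 0.5%), with site vectors sampled from the CLF at a true
\(\theta\) specified on exactly the imputation model's parameterization.
This congeniality is deliberate: it makes parameter recovery a sharp
keystone test (generate at \(K = 2000\), fit, every component of
\(\hat\theta\) within three standard errors of truth), with the small-`n`
enumeration oracle as the non-shared-code cross-check of the sampler
itself.

The `nhanes_like_preset()` coefficients were chosen a priori on
subject-matter grounds (interproximal sites more affected than mid sites,
posterior sextants more than anterior, disease rising steeply with age
and with tooth loss, correlation strongest within a tooth), and the
intercept and overall correlation level were then calibrated once by
simulation at \(K = 3621\) so the full-mouth mean extent is about 19
sites and the prevalence of one-or-more affected sites about 0.89
(`scripts/calibrate_preset.R`); the calibrated values are frozen in the
preset and not revisited. What the generator does *not* emulate: the
joint distribution of real demographic covariates, non-uniform patterns
of tooth loss (molars are lost first in reality; the preset removes a
uniformly random subset), measurement error, or model misspecification.
Consequently, passing the end-to-end tests demonstrates that the
machinery is correct *under a correctly specified imputation model*; it
cannot show how large the bias is under the misspecification real data
would bring, which is exactly the quantity the reference evaluation on
real survey data addresses.

## Evaluation harness

`run_evaluation()` repeats, `reps` times: resample \(K\) mouths with
replacement, mask with the RSSM (sites are the sampling unit, masks are
re-drawn every replicate, technically missing sites remain eligible for
selection), fit, impute, estimate; the gold standard is computed once on
the source cohort. Reported metrics per estimand: percent relative bias
of the point estimator, average and Monte Carlo variance, percent
relative efficiency (full-mouth variance over average replicate
variance), percent relative bias of the variance estimator, and the same
bias for the standard (missing-as-healthy) method on identical
replicates. Replicates whose model fit fails are skipped, counted and
reported. In the full-mouth arm the Taylor variance is reported. Since
real full-mouth examinations carry a sliver of technical missingness, the
harness's full-mouth estimator counts unmeasured sites as unaffected —
exactly what a direct calculation does — while the public
`cohort_estimate()` stays strict and refuses incomplete mouths.

## Problem sizes used by the checks

The test suite exercises the sharp oracles at small sizes (exact pmfs up
to \(n = 6\); 200,000 sampler draws; 1,000-case fuzzing of the
standard-method inequality) and the simulation properties at the sizes we
consider informative yet proportionate for a routine check: parameter
recovery at \(K = 2000\) full mouths, and the direction-of-bias study at
\(K = 1000\) mouths, 100 evaluation replicates, \(m = 84\), \(M = 10\),
\(B = 100\). The acceptance script runs the full-mouth estimates at
\(K = 3621\) and a scaled-down evaluation (\(K = 800\), 50 replicates)
with the same protocol settings. These sizes are the package's own
choices; the reference analysis uses 500 replicates of 3,621 mouths with
\(M = 25\), \(B = 200\), which the same functions accept unchanged.

## Known limitations

* Only random site selection protocols are implemented; fixed-site and
  half-mouth designs would require selections that identify the
  correlation model and are out of scope.
* Only threshold-based indicators are modelled (any threshold label; no
  raw CEJ/probing-depth arithmetic) and only single-stage weighting — no
  survey strata/PSU variance estimation.
* The clamping repair is a stand-in for the original feasibility
  modification; clamp rates are logged so heavy clamping is visible.
* MI-boot variances can underestimate the Monte Carlo variance of the
  estimator (the evaluation harness quantifies this); treat reported
  variances for small `m` with corresponding caution.
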