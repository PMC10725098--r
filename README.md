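# periomi

Multiple imputation for partial-mouth periodontal recording protocols.

## What problem this solves

Periodontitis surveillance compares mouths by **extent** (the number of
tooth sites whose clinical attachment loss meets a threshold, e.g. CAL ≥
3 mm, "CAL3+") and **prevalence** (the share of people with at least *h*
affected sites). The gold standard measures all 6 sites of up to 28
non-third-molar teeth (168 sites). Partial recording protocols measure
only *m* randomly selected sites per mouth and are far cheaper — but
applying the full-mouth case definition directly to partial data
underestimates extent and prevalence severely (specificity 100%,
sensitivity < 100%).

`periomi` instead treats nonselected sites as missing completely at
random and multiply imputes them:

1. **Model** (`fit_gee`): a logistic marginal mean model (site type,
   sextant, log number of teeth, age group) and a linear model for
   within-mouth pairwise correlations (same tooth / adjacent sharing an
   interproximal space / adjacent not sharing it / vertically opposing /
   other, plus log teeth), fitted jointly by paired generalized
   estimating equations with an empirical sandwich covariance for
   θ = (β, α).
2. **Impute** (`impute_cohort`): for each of M replicates, draw
   θ\* ~ MVN(θ̂, V(θ̂)), rebuild each mouth's means μ and correlation
   matrix R, and draw the missing sites sequentially from the
   conditional linear family (CLF) of joint binary distributions,
   conditioning on the observed sites:
   λⱼ = μⱼ + Σⱼ,₁:ⱼ₋₁ Σ₁:ⱼ₋₁⁻¹ (y − μ), clamped into [ε, 1−ε].
3. **Combine** (`mi_estimate`): the weighted ratio estimator
   τ̂ = Σ wᵢSᵢ / Σ wᵢ on each completed data set, a cluster bootstrap
   (B resamples) for the within-imputation variance, and Rubin's rules
   V̂ = V_W + (1 + 1/M)·V_B across replicates (MI-boot).

The package also ships the full simulation evaluation harness
(`run_evaluation`: resample mouths → mask with an RSSM → fit → impute →
estimate, with percent relative bias / efficiency / variance-bias
metrics) and a synthetic full-mouth cohort generator with known truth
(`generate_cohort`, `nhanes_like_preset`), so every stage is testable
without any external data.

## Worked example

```r
library(periomi)

spec   <- nhanes_like_preset()                  # frozen synthetic truth
full   <- generate_cohort(spec, K = 800, seed = 3)
masked <- apply_rssm(full, m = 84, seed = 11)   # 84-site random protocol

fit <- fit_gee(masked)
imp <- impute_cohort(masked, fit, M = 25, seed = 7)
res <- mi_estimate(imp, list(estimand("extent"),
                             estimand("prevalence", 1)),
                   B = 200, seed = 9)
res[["extent"]]
#> MI estimate: 20.5721  (total variance 0.7553 = within 0.7345
#>   + (1 + 1/M) x between 0.02003; M = 25)

# what the biased standard method would have reported on the same mask:
standard_partial_estimate(masked, estimand("extent"))
#> [1] 12.2775

# and the full-mouth value it should match (technical-missing sites,
# about 0.5% here, count as unaffected):
standard_partial_estimate(full, estimand("extent"))
#> [1] 20.34875
```

The MI estimate (20.57, SE about 0.87) sits within sampling error of the
full-mouth value (20.35), while the direct partial-mouth calculation
(12.28) understates extent by roughly 40% — the bias the method exists
to remove. `res[["prevalence(h=1)"]]$point` (0.9082 here) behaves the
same way on the proportion scale.

A thin command-line interface wraps the same functions:

```sh
Rscript inst/cli/perio-impute.R synth --K 800 --seed 3 --out full.csv
Rscript inst/cli/perio-impute.R mask --m 84 --seed 11 --in full.csv --out masked.csv
Rscript inst/cli/perio-impute.R impute --in masked.csv --M 25 --B 200 --seed 7 --out results.json
```

## Scope

Random site selection protocols only (no fixed-site or half-mouth
designs); threshold-based binary indicators only (the threshold is
configurable, default CAL ≥ 3 mm); single-stage weighting without survey
strata/PSU structure; no severity (mean CAL) estimand. See the vignette
(`vignettes/periodontal-mi.Rmd`) for the model details, numerical
choices and known limitations.
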