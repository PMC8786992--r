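---
title: "Methods: quantifying radiomic feature reproducibility across CT reconstruction settings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying radiomic feature reproducibility across CT reconstruction settings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radstab)
```

## The analysis problem

A CT acquisition can be reconstructed at several iterative-reconstruction
(IR) blending levels — 0% (filtered backprojection, FBP), 20%, 40%, 50%,
60%, 80% ASIR are the levels modelled by the default `recon_design()` — and
radiomic features computed from the *same* lesion contour on each
reconstruction need not agree. `radstab` asks, per feature: how large is the
setting-induced variation relative to the between-patient spread, and is it
*systematic* (the same trend in almost every patient, hence predictable and
correctable) or *random*?

Two complementary statistics answer this, and their cross-tabulation drives
everything downstream.

## Concordance: OCCC

For a feature's patients × settings matrix the overall concordance
correlation coefficient is

$$\mathrm{OCCC} = \frac{2\sum_{j<k} S_{jk}}
  {(J-1)\sum_j S_j^2 + \sum_{j<k} (\bar y_j - \bar y_k)^2},$$

a weighted mean of all pairwise Lin CCCs, with weights
$S_j^2 + S_k^2 + (\bar y_j - \bar y_k)^2$. The test suite pins the
implementation to this weighted-pairwise form computed by an independent
brute-force oracle.

Numerical conventions, fixed once and documented here:

* **Divisor-n moments.** Variances and covariances use the divisor-*n*
  (biased) estimators of the classical CCC definition. The choice is not
  cosmetic: the mean-difference terms do not rescale with $n/(n-1)$, so
  divisor-n and divisor-(n−1) give different OCCC values. Exact numerical
  parity with other software therefore depends on its estimator convention.
* **Degenerate inputs.** Two constant, equal vectors have a vanishing
  denominator; perfect agreement (1) is returned with a warning. Constant
  but unequal columns yield a zero numerator over a positive denominator
  and return 0.
* Shape features computed under a single shared segmentation are identical
  across reconstructions, so their OCCC is exactly 1 (identical non-constant
  columns need no convention).

The threshold separating "concordant" from "affected" features defaults to
`occc_threshold = 0.85`, the conventional cut in the CT-radiomics
reproducibility literature; it is a `run_config()` parameter.

## The per-feature mixed model

Each feature is modelled as

$$y_{ij} = \beta_0 + \beta_{setting(j)} + \beta_{scanner(i)}
  + \beta_{voltage(i)} + \beta_v\,vol_i + b_i + e_{ij},$$

with a random patient intercept $b_i \sim N(0, \sigma_s^2)$ absorbing the
within-patient correlation across the six reconstructions, and the setting
entering as a categorical factor against the reference level (FBP by
default), so each non-reference blending level gets one coefficient and one
p value versus the reference. Tumour volume (raw cm³ by default;
`log_volume = TRUE` is available) adjusts for lesion size; features that
*are* the segmented volume (`is_volume_like`, by default only
`original_shape_VoxelVolume`) drop that covariate, since it would be the
response regressed on itself.

**Estimation.** With a single random intercept the REML problem is
one-dimensional: we profile the criterion over the variance ratio
$\lambda = \sigma_s^2/\sigma_e^2$, solving a closed-form generalized
least-squares step per candidate $\lambda$ (per-patient block inverses, so
each evaluation is $O(Np^2)$), and optimize over $\log\lambda \in [-15, 15]$
with the boundary $\lambda = 0$ checked explicitly. This is robust,
dependency-light, and exactly testable: on balanced complete data the
setting coefficients equal the mean paired differences versus the
reference, which the tests assert to 1e-10, and the whole fit is checked
against an independent general-purpose mixed-model implementation to 1e-7.

**Inference.** t statistics with the between-within degrees-of-freedom
convention: within-patient terms (the setting contrasts) use
$N - n_{patients} - n_{within}$; between-patient terms (scanner, voltage,
volume, intercept) use $n_{patients} - n_{between} - 1$. At around 100
patients this is practically indistinguishable from more elaborate df
approximations and is exactly reproducible. Kenward–Roger or Satterthwaite
corrections are deliberately out of scope.

**Degenerate data.** An exact within-patient fit (zero residual noise —
e.g. a noise-free planted shift) drives $\lambda \to \infty$; the engine
detects it from the within-centred residual sum of squares and reports
`var_residual = 0`, with p values by convention 1 for zero coefficients and
0 otherwise. Non-convergence falls back to the ordinary ($\lambda = 0$)
regression with `converged = FALSE`, and such fits are excluded from
harmonization.

**Multiplicity.** `batch_mixed_models()` applies Benjamini–Hochberg within
term families across features: each blending-level contrast forms its own
family (all features' IR80-vs-reference p values adjusted together, and so
on), as do the scanner, voltage and volume terms. This matches how each
reported column of adjusted p values is read — corrected over the features
it compares — and makes a single-feature batch the m = 1 identity. Whether
to adjust within feature families (original/wavelet/LoG) instead is a
legitimate alternative; adjusting within each submitted batch is this
package's fixed convention, and the batch composition is therefore part of
the analysis definition.

## Four-group classification

With `alpha = 0.05` on the FDR-adjusted p:

| | p < 0.05 | p ≥ 0.05 |
|---|---|---|
| **OCCC ≥ 0.85** | group 1: small, systematic | group 2: small, random |
| **OCCC < 0.85** | group 3: large, systematic | group 4: large, random |

Boundary conventions mirror the inequalities literally: OCCC exactly at the
threshold is concordant; p exactly at alpha is *not* significant. The
per-contrast assignment uses that contrast's p; the overall per-feature
group uses the *minimum* adjusted p across contrasts, so a feature counts
as trend-free (group 2/4) only if it is non-significant at every blending
level — the conservative reading of "reproducible without correction".
Group percentages by image type exclude shape features from the
original-image denominator, since their agreement is an artefact of the
shared segmentation rather than evidence of robustness.

## Harmonization

Features in the systematic groups are corrected additively:
$y^{corr}_{ij} = y_{ij} - \hat\beta_{setting(j)}$, reference values
untouched. An additive fixed-effects model implies an additive correction;
a multiplicative variant is out of scope. The correction is in-sample (the
coefficients come from the data being corrected), which matches the
intended use — cleaning a research database before downstream modelling —
but means the corrected data should not be used to re-test the very trend
that was removed. On balanced data the refitted setting coefficients are
zero to numerical precision, the between-patient ordering within each
setting is preserved (the shift is constant per setting), and the OCCC of a
strong-trend feature increases.

## Redundancy clustering

Features (by default the original-image features, at the reference
setting's values) are clustered by complete-linkage agglomeration on the
distance $1 - |\rho_{Spearman}|$, cutting the tree at $1 - 0.75$. Complete
linkage is chosen *because* its merge height is the maximum within-cluster
distance, so the cut provably enforces the stated criterion — every pair
inside a cluster has $|\rho| \ge 0.75$. The guarantee is still audited on
every output rather than assumed. Features are sorted lexicographically
before clustering so linkage ties break deterministically; each cluster's
representative is the member with the highest median absolute correlation
to its cluster mates.

## Rank tests and the baseline table

Scanner and voltage comparisons use the Wilcoxon–Mann–Whitney test at two
representative settings (FBP and IR60 by default — the ends and middle of
the blending range); the sensitivity analysis compares every setting pair
with the Wilcoxon signed-rank test and counts FDR-significant features per
pair. Conventions: zero differences are dropped before ranking (classic
Wilcoxon rather than Pratt, the default of mainstream implementations);
exact null distributions are used up to combined n = 20 (Mann–Whitney) and
n = 25 non-zero pairs (signed-rank) when there are no ties, otherwise the
tie-corrected normal approximation with continuity correction. The baseline
patient-characteristics table uses the chi-square test when all expected
cell counts are at least 5 and the Fisher exact test otherwise (the
conventional switch), and Mann–Whitney for continuous variables, dropping
missing values per variable with counts reported.

## The synthetic generator

`simulate_feature_table()` draws from the generative counterpart of the
analysis model: patient intercepts $N(0, \sigma_s^2)$, a
linear-in-blending-percent setting trend scaled to a per-group maximum and
zeroed at the reference, per-feature scanner/voltage shifts and a tumour
volume slope (all between-patient), an optional patient-by-setting random
interaction, and residual noise. Tumour volumes are log-normal
(meanlog log 30, sdlog 0.6) truncated to the 5–200 cm³ inclusion window;
103 patients split roughly 50/50 over two scanner models and two voltages
mirror the modelled study population.

The four planting regimes operationalize the group definitions (effect
sizes in units of the between-patient SD, fixed from the moment
approximation of the expected OCCC before any recovery test was run, and
frozen):

* group 1: max |β| = 0.3, residual SD 0.1 — expected OCCC ≈ 0.98, trend
  detectable at n ≈ 100;
* group 2: β = 0, residual SD 0.1 — expected OCCC ≈ 0.99;
* group 3: max |β| = 2.0 — expected OCCC ≈ 0.6;
* group 4: β = 0, interaction SD 1.5 — expected OCCC ≈ 0.3 with no common
  trend.

`synthetic_config()` validates that the requested parameters are consistent
with their planted group via the same moment approximation and rejects
contradictory presets (e.g. group 2 with a huge residual). Shape features
are generated constant across settings; the `redundancy` preset adds exact
monotone transforms of a base feature for clustering tests.

**What the generator does not emulate** — and hence what passing recovery
tests do and do not show: real features are heavily inter-correlated
(simulated ones are independent except for the deliberate redundant
copies), real trends need not be linear in the blending percentage
(arbitrary per-setting coefficients are supported but not the preset
default), noise is Gaussian and homoscedastic, and there are no outliers,
segmentation errors or missing reconstructions. Recovery rates on the
presets demonstrate the pipeline's correctness and power under its own
model, not the prevalence of any group in clinical data.

## Problem sizes in the test suite

The recovery and calibration checks run at the modelled study scale —
103 patients × 6 settings, 25 features per homogeneous preset — with 50
seeds for group recovery, 500 replicates (100 patients) for mixed-model
bias and confidence-interval coverage, 200 replicates for the harmonization
gain, and 1000 random matrices / 200 enumerated datasets for the OCCC and
exact-test oracles. The paper-shaped preset uses 100 planted features plus
4 shape features: large enough to exercise every category facet and the
FDR machinery, small enough to keep a full pipeline run around ten seconds.

## Known limitations

* One random intercept only: no random slopes, crossed effects, or
  non-Gaussian responses.
* Harmonization assumes the additive model and pooled coefficients; no
  per-subpopulation or cross-fitted correction.
* FDR scope is per submitted batch; analyses mixing image types in one
  batch adjust across all of them.
* The complete-case rule within each requested setting subset is this
  package's convention for incomplete tables; the modelled design is
  complete by construction.
* OCCC is reported as a point value; confidence intervals for agreement
  indices are out of scope.
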