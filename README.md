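# radstab

Reproducibility of radiomic features across CT reconstruction settings.

## The problem

Radiomic analyses extract hundreds to thousands of quantitative features
(shape, intensity histogram, texture-matrix statistics) from segmented
lesions on CT images. The same raw acquisition can be reconstructed at
different iterative-reconstruction (IR) blending levels — 0% (pure filtered
backprojection, FBP) up to 80% ASIR — and many features shift with that
choice, silently confounding any downstream model built on a heterogeneous
clinical archive. `radstab` implements an integrative pipeline that
quantifies this sensitivity per feature, separates *systematic* from
*random* setting dependence, corrects the correctable features, and measures
feature redundancy. It is aimed at radiomics researchers validating feature
panels on multi-protocol CT databases.

## The statistics at the core

For each feature, with patients *i* and reconstruction settings *j = 1..J*:

**Overall concordance correlation coefficient (OCCC)** — agreement of the
per-patient values across all J settings,

    OCCC = 2 Σ_{j<k} S_jk / [ (J−1) Σ_j S_j² + Σ_{j<k} (ȳ_j − ȳ_k)² ]

with divisor-n moment estimators; at J = 2 this is Lin's CCC. OCCC ≥ 0.85
flags a feature whose setting-induced variation is small relative to the
between-patient spread.

**Linear mixed model** — a random patient intercept plus fixed effects for
the setting (categorical, FBP reference), scanner model, tube voltage and
tumour volume:

    y_ij = β₀ + β_setting(j) + β_scanner(i) + β_voltage(i) + β_v·vol_i + b_i + e_ij

estimated by profiled REML over the variance ratio σ²_s/σ²_e, with
between-within degrees of freedom for the t tests. One coefficient and p
value per non-reference blending level measures the *systematic* shift
versus FBP. All p values are Benjamini–Hochberg FDR-adjusted across
features; adjusted p < 0.05 is significant.

**Four-group classification** — the OCCC (≥/< 0.85) by significance
(p </≥ 0.05) cross-tabulation:
group 1 = small systematic (correctable), group 2 = small random
(reproducible as is), group 3 = large systematic (rescued by harmonization),
group 4 = large random (rejected).

**Harmonization** subtracts each fitted setting coefficient from the values
observed at that setting; **redundancy clustering** groups features by
complete linkage on 1 − |Spearman ρ| cut so every intra-cluster pair has
|ρ| ≥ 0.75.

Because clinical image sets are rarely shareable, the package ships a
synthetic generator (`simulate_feature_table()`) that plants features of all
four groups with known coefficients, so every stage is testable by
parameter recovery.

## Worked example

```r
library(radstab)

sim <- simulate_feature_table(synthetic_preset("paper_shaped", seed = 42))
sim$table
#> <feature_table> 103 patients x 6 settings x 104 features (0 missing cells)

occ <- occc_features(sim$table)                  # per-feature OCCC
mm  <- batch_mixed_models(sim$table)             # per-feature mixed models
cls <- classify_features(occ, setting_contrasts(mm))
dplyr::count(overall_groups(cls), group)
#> # A tibble: 4 × 2
#>   group     n
#> 1     1    31
#> 2     2    23
#> 3     3    28
#> 4     4    22
```

104 simulated features (100 planted in the four groups plus 4 shape
features) are classified from their concordance and their FDR-adjusted
setting contrasts. A single fit shows the estimated blending-level trend —
here a feature with a small but highly systematic shift (about +0.28 at
IR80 versus FBP, within-patient SD ≈ 0.11):

```r
fit_feature_mixed_model(sim$table, "original_firstorder_Sim001")
#> <feature_mm> original_firstorder_Sim001: 618 obs / 103 patients;
#>              var_subject = 1.046, var_residual = 0.01119
#>   term         setting  estimate std_error    df statistic  p_value
#> 1 (Intercept)  NA        -4.31      0.235      99   -18.3   1.35e-33
#> 2 settingIR20  IR20       0.0520    0.0147    510     3.53  4.59e- 4
#> ...
#> 6 settingIR80  IR80       0.277     0.0147    510    18.8   2.09e-60
```

Harmonizing a group-3 feature (large systematic trend) restores its
concordance:

```r
ov <- overall_groups(cls)
f3 <- ov$feature[ov$group == 3][1]
h  <- harmonize(sim$table, mm, f3)
occc_features(h$table)$occc[occ$feature == f3]   # 0.99, was 0.65
```

`run_pipeline(run_config(...))` chains all stages and writes the CSV/JSON
report bundle; `autoplot()` on the classification, `plot_occc()`,
`plot_pairwise_counts()` and `plot_before_after()` draw the standard
figures.

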