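Package: radstab
Title: Reproducibility of Radiomic Features Across CT Reconstruction Settings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative pipeline for assessing the robustness of radiomic
    features against CT iterative-reconstruction blending levels. Quantifies
    agreement across reconstruction settings with the overall concordance
    correlation coefficient (OCCC), fits per-feature linear mixed models with
    a random patient intercept to isolate systematic setting, scanner, tube
    voltage and tumour-volume effects, applies Benjamini-Hochberg false
    discovery rate correction, cross-classifies features into four
    reproducibility groups, removes systematic setting trends by
    coefficient-based harmonization, and quantifies feature redundancy by
    Spearman-correlation clustering. Includes a synthetic feature-table
    generator with planted ground truth so every stage is testable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    withr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
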