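#' Four-group reproducibility classification
#'
#' Cross-classifies each feature by its overall concordance (OCCC) and the
#' FDR-adjusted mixed-model p value of each reconstruction-setting contrast:
#'
#' * group 1 — OCCC >= threshold and p < alpha: small but systematic setting
#'   dependence (predictable, correctable);
#' * group 2 — OCCC >= threshold and p >= alpha: small, random variation
#'   (reproducible as is);
#' * group 3 — OCCC < threshold and p < alpha: large systematic trend
#'   (correctable by harmonization);
#' * group 4 — OCCC < threshold and p >= alpha: large random variation
#'   (not correctable).
#'
#' Boundary convention: OCCC exactly at the threshold takes the ">="
#' branch; p exactly at alpha counts as non-significant.
#'
#' @param occc_tbl Output of [occc_features()] (columns `feature`, `occc`).
#' @param contrast_tbl Output of [setting_contrasts()] (columns `feature`,
#'   `setting`, `p_fdr`).
#' @param occc_threshold OCCC cut (default 0.85).
#' @param alpha Significance level on the FDR-adjusted p (default 0.05).
#' @return An object of class `repro_classification`: a tibble with one row
#'   per (feature, setting contrast): `feature`, `setting`, `occc`, `p_fdr`,
#'   `group` (integer 1-4). Features lacking either ingredient are dropped
#'   with a warning. Thresholds are carried as attributes.
#' @export
classify_features <- function(occc_tbl, contrast_tbl,
                              occc_threshold = 0.85, alpha = 0.05) {
  if (occc_threshold <= 0 || occc_threshold > 1 || alpha <= 0 || alpha > 1) {
    stop("thresholds must lie in (0, 1]", call. = FALSE)
  }
  occ <- occc_tbl[!is.na(occc_tbl$occc), c("feature", "occc")]
  ctr <- contrast_tbl[!is.na(contrast_tbl$p_fdr),
                      c("feature", "setting", "p_fdr")]
  dropped <- union(setdiff(occc_tbl$feature, ctr$feature),
                   setdiff(unique(contrast_tbl$feature), occ$feature))
  if (length(dropped)) {
    warning(length(dropped), " feature(s) lacked an OCCC or a usable ",
            "contrast p value and were omitted", call. = FALSE)
  }
  out <- dplyr::inner_join(ctr, occ, by = "feature")
  out$group <- classify_group(out$occc, out$p_fdr, occc_threshold, alpha)
  out <- out[c("feature", "setting", "occc", "p_fdr", "group")]
  out <- tibble::new_tibble(out, class = "repro_classification")
  attr(out, "occc_threshold") <- occc_threshold
  attr(out, "alpha") <- alpha
  out
}

#' @noRd
classify_group <- function(occc, p, occc_threshold, alpha) {
  concordant <- occc >= occc_threshold
  significant <- p < alpha
  ifelse(concordant, ifelse(significant, 1L, 2L),
         ifelse(significant, 3L, 4L))
}

#' Overall (across-contrast) group per feature
#'
#' A feature's overall group uses the minimum FDR-adjusted p across its
#' setting contrasts: a feature is declared free of a systematic trend
#' (group 2/4) only when it is non-significant at every blending level.
#'
#' @param assignments A `repro_classification` from [classify_features()].
#' @return Tibble with one row per feature: `feature`, `occc`, `min_p_fdr`,
#'   `group`.
#' @export
overall_groups <- function(assignments) {
  stopifnot(inherits(assignments, "repro_classification"))
  thr <- attr(assignments, "occc_threshold")
  alpha <- attr(assignments, "alpha")
  assignments |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(occc = .data$occc[[1L]],
                     min_p_fdr = min(.data$p_fdr), .groups = "drop") |>
    dplyr::mutate(group = classify_group(.data$occc, .data$min_p_fdr,
                                         thr, alpha))
}

#' Group percentages by image type
#'
#' Percentage of features in each of the four reproducibility groups, per
#' image type and per setting contrast. For the original images the shape
#' features are excluded from the denominator (under a shared segmentation
#' their values are identical across reconstructions by construction).
#'
#' @param assignments A `repro_classification` from [classify_features()].
#' @param features Feature descriptor tibble (e.g. `table$features`).
#' @param contrasts Setting contrasts to tabulate (default all present).
#' @return Tibble with `image_type`, `setting`, `group`, `n`, `percent`;
#'   percentages sum to 100 within each (image_type, setting).
#' @export
group_counts <- function(assignments, features, contrasts = NULL) {
  stopifnot(inherits(assignments, "repro_classification"))
  if (!nrow(assignments)) stop("no assignments", call. = FALSE)
  x <- dplyr::inner_join(tibble::as_tibble(assignments), features,
                         by = c(feature = "name"))
  if (!is.null(contrasts)) x <- x[x$setting %in% contrasts, ]
  x <- x[!(x$image_type == "original" & x$category == "shape"), ]
  x |>
    dplyr::count(.data$image_type, .data$setting, .data$group) |>
    tidyr::complete(tidyr::nesting(image_type, setting), group = 1:4,
                    fill = list(n = 0L)) |>
    dplyr::group_by(.data$image_type, .data$setting) |>
    dplyr::mutate(percent = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}

#' Per-feature scatter records for one contrast
#'
#' The data behind an OCCC-versus-p scatter plot: one point per feature at a
#' given setting contrast, with its category and group.
#'
#' @param assignments A `repro_classification`.
#' @param features Feature descriptor tibble.
#' @param contrast Setting contrast label (must be present).
#' @return Tibble with `feature`, `occc`, `p_fdr`, `image_type`, `category`,
#'   `group`.
#' @export
scatter_export <- function(assignments, features, contrast) {
  stopifnot(inherits(assignments, "repro_classification"))
  x <- assignments[assignments$setting == contrast, ]
  if (!nrow(x)) stop("no assignments for contrast ", contrast, call. = FALSE)
  dplyr::inner_join(tibble::as_tibble(x), features,
                    by = c(feature = "name")) |>
    dplyr::select("feature", "occc", "p_fdr", "image_type", "category",
                  "group")
}

#' Plot OCCC against FDR-adjusted p for one or more contrasts
#'
#' Scatter of per-feature OCCC versus mixed-model FDR-adjusted p value, with
#' dotted threshold lines dividing the plane into the four reproducibility
#' groups.
#'
#' @param object A `repro_classification`.
#' @param ... Unused.
#' @return A ggplot object, faceted by setting contrast.
#' @method autoplot repro_classification
#' @export
autoplot.repro_classification <- function(object, ...) {
  thr <- attr(object, "occc_threshold")
  alpha <- attr(object, "alpha")
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$p_fdr, y = .data$occc,
                               colour = factor(.data$group))) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dotted", colour = "red") +
    ggplot2::geom_vline(xintercept = alpha, linetype = "dotted", colour = "red") +
    ggplot2::facet_wrap(~setting) +
    ggplot2::labs(x = "FDR-adjusted p value", y = "OCCC", colour = "group") +
    ggplot2::theme_minimal()
}
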