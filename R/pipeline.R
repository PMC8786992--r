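#' Run configuration for the full reproducibility pipeline
#'
#' Bundles everything [run_pipeline()] needs: the data source (CSV paths or a
#' synthetic configuration), the setting subset and reference, and the
#' analysis thresholds.
#'
#' @param input Either a [synthetic_config()] / preset name, or a list
#'   `list(values = <csv path>, metadata = <csv path>)`.
#' @param design A [recon_design()] describing the input settings.
#' @param settings Setting subset analysed (default: all in the design).
#' @param reference Reference setting for the mixed models (default: the
#'   design's; must belong to `settings`).
#' @param restricted Optional second setting subset rerun, as
#'   `list(settings = ..., reference = ...)`; default is the clinically used
#'   IR40-IR80 range with IR40 as reference when those settings exist, else
#'   `NULL`.
#' @param occc_threshold,alpha,spearman_threshold Analysis thresholds
#'   (defaults 0.85, 0.05, 0.75).
#' @param univariate_settings Representative settings for the scanner /
#'   voltage univariate comparison (default FBP and IR60 when present).
#' @param harmonize_groups Overall groups whose features are harmonized
#'   (default 1 and 3: the correctable, systematic ones).
#' @param seed Integer seed (synthetic generation).
#' @param output_dir Directory for the CSV/JSON report bundle; `NULL`
#'   computes everything in memory without writing.
#' @return A list of class `run_config`.
#' @export
run_config <- function(input = synthetic_preset("paper_shaped"),
                       design = recon_design(),
                       settings = NULL, reference = NULL,
                       restricted = NULL,
                       occc_threshold = 0.85, alpha = 0.05,
                       spearman_threshold = 0.75,
                       univariate_settings = NULL,
                       harmonize_groups = c(1L, 3L),
                       seed = 1L, output_dir = NULL) {
  if (is.character(input)) input <- synthetic_preset(input, seed = seed)
  if (inherits(input, "synthetic_config")) design <- input$design
  if (is.null(settings)) settings <- design$settings
  if (is.null(reference)) reference <- design$reference
  if (!all(settings %in% design$settings)) {
    stop("`settings` must be a subset of the design", call. = FALSE)
  }
  if (!reference %in% settings) {
    stop("`reference` must belong to the analysed settings", call. = FALSE)
  }
  if (is.null(restricted)) {
    sub <- intersect(c("IR40", "IR50", "IR60", "IR80"), settings)
    if (length(sub) >= 2L && "IR40" %in% sub) {
      restricted <- list(settings = sub, reference = "IR40")
    }
  }
  if (!is.null(restricted)) {
    if (!all(restricted$settings %in% settings) ||
        !restricted$reference %in% restricted$settings) {
      stop("invalid restricted subset", call. = FALSE)
    }
  }
  if (is.null(univariate_settings)) {
    univariate_settings <- intersect(c("FBP", "IR60"), settings)
    if (!length(univariate_settings)) univariate_settings <- settings[[1L]]
  }
  for (thr in c(occc_threshold, alpha, spearman_threshold)) {
    if (thr <= 0 || thr > 1) stop("thresholds must lie in (0, 1]", call. = FALSE)
  }
  structure(
    list(input = input, design = design, settings = settings,
         reference = reference, restricted = restricted,
         occc_threshold = occc_threshold, alpha = alpha,
         spearman_threshold = spearman_threshold,
         univariate_settings = univariate_settings,
         harmonize_groups = as.integer(harmonize_groups),
         seed = as.integer(seed), output_dir = output_dir),
    class = "run_config"
  )
}

#' Run the full reproducibility pipeline
#'
#' Executes every stage on one feature table: baseline patient comparison,
#' univariate scanner/voltage tests, per-feature OCCC (full and restricted
#' setting subsets) with category medians, per-feature mixed models with
#' FDR-adjusted contrasts, the four-group classification with percentage
#' tables and scatter exports, the pairwise signed-rank sensitivity counts,
#' harmonization of the systematically affected features with a
#' before/after report, and Spearman redundancy clustering of the original
#' features at the reference setting.
#'
#' When `config$output_dir` is set, each result is written as a CSV (the
#' pairwise counts and the manifest as JSON-friendly tables) so that every
#' reported number traces to exactly one file.
#'
#' @param config A [run_config()].
#' @return Invisibly, a named list with elements `table`, `truth` (NULL for
#'   CSV input), `baseline`, `univariate`, `occc`, `occc_medians`,
#'   `occc_restricted`, `mixed_models` (`mm_batch`), `assignments`,
#'   `overall`, `group_percentages`, `scatter`, `pairwise_counts`,
#'   `harmonized`, `before_after`, `clusters`, `manifest`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  truth <- NULL
  if (inherits(config$input, "synthetic_config")) {
    sim <- simulate_feature_table(config$input, seed = config$seed)
    table <- sim$table
    truth <- sim$truth
  } else {
    table <- read_feature_table(config$input$values, config$input$metadata,
                                config$design)
  }

  baseline <- dplyr::bind_rows(
    dplyr::mutate(baseline_comparison(table$patients, "scanner"),
                  grouping = "scanner", .before = 1L),
    dplyr::mutate(baseline_comparison(table$patients, "tube_voltage"),
                  grouping = "tube_voltage", .before = 1L)
  )

  univariate <- dplyr::bind_rows(
    univariate_group_tests(table, "scanner", config$univariate_settings),
    univariate_group_tests(table, "tube_voltage", config$univariate_settings)
  )

  occ <- occc_features(table, config$settings, config$occc_threshold)
  occ_med <- occc_category_medians(occ, table$features)
  occ_restricted <- NULL
  if (!is.null(config$restricted)) {
    occ_restricted <- occc_features(table, config$restricted$settings,
                                    config$occc_threshold)
  }

  mm <- batch_mixed_models(table, settings = config$settings,
                           reference = config$reference)
  contrasts <- setting_contrasts(mm)
  assignments <- classify_features(occ, contrasts,
                                   config$occc_threshold, config$alpha)
  overall <- overall_groups(assignments)
  pct <- group_counts(assignments, table$features)
  scatter <- purrr::map_dfr(
    unique(assignments$setting),
    function(ct) dplyr::mutate(scatter_export(assignments, table$features, ct),
                               setting = ct, .after = 1L)
  )

  pairwise <- pairwise_algorithm_counts(table, alpha = config$alpha,
                                        image_type = "original",
                                        settings = config$settings)

  to_fix <- overall$feature[overall$group %in% config$harmonize_groups]
  harmonized <- NULL; before_after <- NULL
  if (length(to_fix)) {
    harmonized <- suppressWarnings(harmonize(table, mm, to_fix))
    g3 <- overall$feature[overall$group == 3L]
    example <- if (length(g3)) g3[[1L]] else to_fix[[1L]]
    before_after <- dplyr::mutate(
      before_after_report(table, harmonized, example),
      feature = example, .before = 1L
    )
  }

  originals <- table$features$name[table$features$image_type == "original"]
  clusters <- NULL
  if (length(originals) >= 2L) {
    rho <- suppressWarnings(
      spearman_matrix(table, config$reference, originals)
    )
    clusters <- cluster_features(rho, config$spearman_threshold)
  }

  manifest <- list(
    package = "radstab",
    version = as.character(utils::packageVersion("radstab")),
    seed = config$seed,
    settings = config$settings, reference = config$reference,
    occc_threshold = config$occc_threshold, alpha = config$alpha,
    spearman_threshold = config$spearman_threshold,
    n_patients = nrow(table$patients), n_features = nrow(table$features),
    n_missing_cells = n_missing_cells(table),
    synthetic = !is.null(truth)
  )

  out <- list(table = table, truth = truth, baseline = baseline,
              univariate = univariate, occc = occ, occc_medians = occ_med,
              occc_restricted = occ_restricted, mixed_models = mm,
              assignments = assignments, overall = overall,
              group_percentages = pct, scatter = scatter,
              pairwise_counts = pairwise, harmonized = harmonized,
              before_after = before_after, clusters = clusters,
              manifest = manifest)

  if (!is.null(config$output_dir)) {
    write_report_bundle(out, config$output_dir)
  }
  invisible(out)
}

#' @noRd
write_report_bundle <- function(out, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(x, name) {
    if (!is.null(x)) readr::write_csv(x, file.path(dir, paste0(name, ".csv")))
  }
  wr(out$baseline, "baseline")
  wr(out$univariate, "univariate_tests")
  wr(out$occc, "occc")
  wr(out$occc_medians, "occc_category_medians")
  wr(out$occc_restricted, "occc_restricted")
  wr(out$mixed_models$terms, "mixed_model_terms")
  wr(tibble::as_tibble(out$assignments), "group_assignments")
  wr(out$overall, "overall_groups")
  wr(out$group_percentages, "group_percentages")
  wr(out$scatter, "scatter")
  pc <- tibble::as_tibble(out$pairwise_counts, rownames = "setting")
  wr(pc, "pairwise_counts")
  if (!is.null(out$harmonized)) {
    readr::write_csv(out$harmonized$table$values,
                     file.path(dir, "harmonized_values.csv"))
    wr(out$harmonized$coefficients, "harmonization_coefficients")
  }
  wr(out$before_after, "before_after")
  wr(out$clusters, "clusters")
  jsonlite::write_json(out$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Heatmap of pairwise significant-feature counts
#'
#' @param counts Matrix from [pairwise_algorithm_counts()].
#' @return A ggplot tile heatmap.
#' @export
plot_pairwise_counts <- function(counts) {
  d <- tibble::as_tibble(counts, rownames = "setting_a") |>
    tidyr::pivot_longer(-"setting_a", names_to = "setting_b",
                        values_to = "n")
  d$setting_a <- factor(d$setting_a, levels = rownames(counts))
  d$setting_b <- factor(d$setting_b, levels = colnames(counts))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$setting_a, y = .data$setting_b,
                                  fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = "significant\nfeatures") +
    ggplot2::theme_minimal()
}

#' Boxplots of per-feature OCCC by image type and category
#'
#' @param occc_tbl Output of [occc_features()].
#' @param features Feature descriptor tibble.
#' @param occc_threshold Horizontal threshold line (default 0.85).
#' @return A ggplot object.
#' @export
plot_occc <- function(occc_tbl, features, occc_threshold = 0.85) {
  d <- dplyr::inner_join(occc_tbl, features, by = c(feature = "name"))
  d <- d[!is.na(d$occc), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$category, y = .data$occc)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::geom_hline(yintercept = occc_threshold, linetype = "dotted",
                        colour = "red") +
    ggplot2::facet_wrap(~image_type) +
    ggplot2::labs(x = "feature category", y = "OCCC") +
    ggplot2::theme_minimal()
}
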