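#' Coefficient-based harmonization of setting-dependent features
#'
#' Removes the systematic reconstruction-setting trend from selected features
#' by subtracting, from every observed value at a non-reference setting, the
#' mixed-model coefficient fitted for that setting contrast. Values at the
#' reference setting are left bit-identical. Because the correction is a
#' per-setting constant shift, the between-patient ordering within each
#' setting is preserved; on balanced complete data a refit of the mixed model
#' on the corrected values yields setting coefficients of zero.
#'
#' @param table A [feature_table()] (the data the coefficients were fitted
#'   on; in-sample correction).
#' @param batch An `mm_batch` from [batch_mixed_models()], providing one
#'   coefficient per (feature, non-reference setting).
#' @param features Features to correct (default: every feature with a
#'   converged fit in `batch`). Features with a non-converged fit or with a
#'   missing coefficient for a present setting are skipped with a warning.
#' @return An object of class `harmonized_features`: list with `table` (the
#'   corrected [feature_table()]), `coefficients` (tibble of applied shifts,
#'   zero at the reference), `reference`, `skipped` (character).
#' @export
harmonize <- function(table, batch, features = NULL) {
  stopifnot(inherits(table, "feature_table"), inherits(batch, "mm_batch"))
  if (is.null(features)) features <- names(batch$fits)
  ref <- NULL
  skipped <- character(0)
  coefs <- list()
  values <- table$values
  present_settings <- unique(values$setting)
  for (f in features) {
    fit <- batch$fits[[f]]
    if (is.null(fit) || !fit$converged) {
      skipped <- c(skipped, f)
      warning("no converged fit for feature ", f, "; skipped", call. = FALSE)
      next
    }
    if (is.null(ref)) ref <- fit$reference
    shift <- fit$terms$estimate[fit$terms$type == "within"]
    names(shift) <- fit$terms$setting[fit$terms$type == "within"]
    needed <- setdiff(intersect(present_settings, fit$settings), fit$reference)
    if (!all(needed %in% names(shift))) {
      skipped <- c(skipped, f)
      warning("missing coefficient for a present setting in feature ", f,
              "; skipped", call. = FALSE)
      next
    }
    shift <- c(shift, stats::setNames(0, fit$reference))
    rows <- values$feature == f & values$setting %in% names(shift)
    values$value[rows] <- values$value[rows] - shift[values$setting[rows]]
    coefs[[f]] <- tibble::tibble(feature = f, setting = names(shift),
                                 coefficient = unname(shift))
  }
  out_tab <- feature_table(values, table$patients, table$features,
                           table$design)
  structure(
    list(table = out_tab,
         coefficients = dplyr::bind_rows(coefs),
         reference = if (is.null(ref)) table$design$reference else ref,
         skipped = skipped),
    class = "harmonized_features"
  )
}

#' @export
print.harmonized_features <- function(x, ...) {
  cat("<harmonized_features> ", length(unique(x$coefficients$feature)),
      " feature(s) corrected against reference ", x$reference,
      if (length(x$skipped)) paste0(" (", length(x$skipped), " skipped)"),
      "\n", sep = "")
  invisible(x)
}

#' Per-setting distribution summaries before and after harmonization
#'
#' Boxplot-style five-number-plus-mean summaries of one feature's values at
#' each reconstruction setting, before and after the correction.
#'
#' @param original The uncorrected [feature_table()].
#' @param harmonized A `harmonized_features` from [harmonize()].
#' @param feature Feature name, present in both tables.
#' @return Tibble with `stage` ("before"/"after"), `setting`, `min`, `q1`,
#'   `median`, `mean`, `q3`, `max`, `n`.
#' @export
before_after_report <- function(original, harmonized, feature) {
  stopifnot(inherits(original, "feature_table"),
            inherits(harmonized, "harmonized_features"))
  if (!feature %in% original$features$name ||
      !feature %in% harmonized$table$features$name) {
    stop("feature not present in both tables: ", feature, call. = FALSE)
  }
  summarise_one <- function(tab, stage) {
    tab$values[tab$values$feature == feature, ] |>
      dplyr::group_by(setting = .data$setting) |>
      dplyr::summarise(min = min(.data$value),
                       q1 = stats::quantile(.data$value, 0.25, names = FALSE),
                       median = stats::median(.data$value),
                       mean = mean(.data$value),
                       q3 = stats::quantile(.data$value, 0.75, names = FALSE),
                       max = max(.data$value), n = dplyr::n(),
                       .groups = "drop") |>
      dplyr::mutate(stage = stage, .before = 1L)
  }
  dplyr::bind_rows(summarise_one(original, "before"),
                   summarise_one(harmonized$table, "after"))
}

#' Boxplots of a feature's values by setting, before and after harmonization
#'
#' @param original The uncorrected [feature_table()].
#' @param harmonized A `harmonized_features`.
#' @param feature Feature name.
#' @return A ggplot object (two panels: before, after).
#' @export
plot_before_after <- function(original, harmonized, feature) {
  d <- dplyr::bind_rows(
    dplyr::mutate(original$values[original$values$feature == feature, ],
                  stage = "before"),
    dplyr::mutate(
      harmonized$table$values[harmonized$table$values$feature == feature, ],
      stage = "after")
  )
  d$stage <- factor(d$stage, levels = c("before", "after"))
  d$setting <- factor(d$setting, levels = original$design$settings)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$setting, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 18) +
    ggplot2::facet_wrap(~stage) +
    ggplot2::labs(x = "reconstruction setting", y = feature) +
    ggplot2::theme_minimal()
}
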