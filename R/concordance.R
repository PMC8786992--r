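#' Lin's concordance correlation coefficient
#'
#' Agreement between two measurement vectors, combining precision
#' (correlation) and accuracy (closeness of means and variances):
#' \deqn{ccc = 2 S_{xy} / (S_x^2 + S_y^2 + (\bar x - \bar y)^2)}
#' with moment estimators using divisor *n*. The divisor matters: the
#' location-shift term does not rescale with n/(n-1), so the classical
#' divisor-n form is used throughout and [occc()] follows the same
#' convention.
#'
#' @param x,y Numeric vectors of equal length (n >= 2).
#' @return A single value in `[-1, 1]`. When both vectors are constant and
#'   equal, all denominator terms vanish and perfect agreement (1) is
#'   returned with a warning.
#' @examples
#' ccc(c(1, 2, 3, 4), c(2, 3, 4, 5)) # location shift only: 0.714...
#' @export
ccc <- function(x, y) {
  if (length(x) != length(y)) {
    stop("`x` and `y` must have equal length", call. = FALSE)
  }
  n <- length(x)
  if (n < 2L) stop("need at least 2 observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  mx <- mean(x); my <- mean(y)
  sx <- mean((x - mx)^2)
  sy <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  denom <- sx + sy + (mx - my)^2
  if (denom == 0) {
    warning("both vectors constant and equal; CCC defined as 1", call. = FALSE)
    return(1)
  }
  2 * sxy / denom
}

#' Overall concordance correlation coefficient (OCCC)
#'
#' Multi-rater generalization of Lin's CCC across J >= 2 columns (here:
#' reconstruction settings), equal to a weighted mean of all pairwise CCCs:
#' \deqn{occc = \frac{2 \sum_{j<k} S_{jk}}
#'   {(J-1)\sum_j S_j^2 + \sum_{j<k} (\bar y_j - \bar y_k)^2}}
#' with divisor-n moment estimators, matching [ccc()] exactly at J = 2.
#'
#' @param matrix Numeric matrix, patients in rows, settings in columns; no
#'   missing entries.
#' @return A single value `<= 1`. Identical nonconstant columns give exactly
#'   1; an all-constant-equal matrix returns 1 with a warning (degenerate
#'   perfect agreement); constant but unequal columns return 0.
#' @examples
#' m <- cbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(2, 3, 4, 5))
#' occc(m) # 7.5 / 9.5
#' @export
occc <- function(matrix) {
  m <- as.matrix(matrix)
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("missing values not allowed", call. = FALSE)
  n <- nrow(m); J <- ncol(m)
  if (n < 2L) stop("need at least 2 subjects", call. = FALSE)
  if (J < 2L) stop("need at least 2 settings", call. = FALSE)
  mu <- colMeans(m)
  centred <- sweep(m, 2L, mu)
  S <- crossprod(centred) / n            # divisor-n covariance matrix
  sum_cov <- (sum(S) - sum(diag(S))) / 2
  sum_var <- sum(diag(S))
  mean_diff2 <- sum(outer(mu, mu, "-")[upper.tri(S)]^2)
  denom <- (J - 1) * sum_var + mean_diff2
  if (denom == 0) {
    warning("all columns constant and equal; OCCC defined as 1", call. = FALSE)
    return(1)
  }
  2 * sum_cov / denom
}

#' Per-feature OCCC over a setting subset
#'
#' Computes the OCCC of every feature across the requested reconstruction
#' settings, using the complete-case patients for that subset. Features whose
#' matrix cannot be formed (e.g. no complete-case patient) are recorded as
#' failed rather than aborting the batch.
#'
#' @param table A [feature_table()].
#' @param settings Setting labels to compare (>= 2; default all).
#' @param occc_threshold Threshold used only to fill the convenience flag
#'   column `occc_lt_threshold` (default 0.85).
#' @return Tibble with one row per feature: `feature`, `n_subjects`, `occc`,
#'   `occc_lt_threshold`, `error` (NA when the computation succeeded).
#' @export
occc_features <- function(table, settings = table$design$settings,
                          occc_threshold = 0.85) {
  stopifnot(inherits(table, "feature_table"))
  if (length(settings) < 2L) {
    stop("need at least 2 settings", call. = FALSE)
  }
  one <- function(f) {
    res <- tryCatch({
      m <- feature_matrix(table, f, settings)
      val <- withCallingHandlers(
        occc(m),
        warning = function(w) invokeRestart("muffleWarning")
      )
      tibble::tibble(feature = f, n_subjects = nrow(m), occc = val,
                     error = NA_character_)
    }, error = function(e) {
      tibble::tibble(feature = f, n_subjects = NA_integer_, occc = NA_real_,
                     error = conditionMessage(e))
    })
    res
  }
  out <- purrr::map_dfr(table$features$name, one)
  out$occc_lt_threshold <- !is.na(out$occc) & out$occc < occc_threshold
  out[c("feature", "n_subjects", "occc", "occc_lt_threshold", "error")]
}

#' Median OCCC by image type and feature category
#'
#' Summary analogous to a per-category concordance table: median OCCC within
#' each image type / subtype / category cell.
#'
#' @param occc_tbl Output of [occc_features()].
#' @param features Feature descriptor tibble (e.g. `table$features`).
#' @param by_subtype Also split wavelet bands / LoG sigmas (default TRUE).
#' @return Tibble with `image_type`, optionally `image_subtype`, `category`,
#'   `n_features`, `median_occc`.
#' @export
occc_category_medians <- function(occc_tbl, features, by_subtype = TRUE) {
  joined <- dplyr::inner_join(occc_tbl, features,
                              by = c(feature = "name"))
  keys <- c("image_type", if (by_subtype) "image_subtype", "category")
  joined |>
    dplyr::filter(!is.na(.data$occc)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(n_features = dplyr::n(),
                     median_occc = stats::median(.data$occc),
                     .groups = "drop")
}
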