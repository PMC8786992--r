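#' Wilcoxon-Mann-Whitney two-sample test
#'
#' Two-sided rank-sum comparison of two independent groups. The exact null
#' distribution is used when the combined sample size is at most 20 and there
#' are no ties; otherwise the normal approximation with tie and continuity
#' correction.
#'
#' @param group_a,group_b Numeric vectors (each nonempty, combined n >= 3).
#' @return Tibble with `statistic` (Mann-Whitney U for the first group),
#'   `p_value`, `exact` (logical).
#' @export
mann_whitney <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b)) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  n <- length(group_a) + length(group_b)
  if (n < 3L) stop("combined sample size must be at least 3", call. = FALSE)
  ties <- anyDuplicated(c(group_a, group_b)) > 0L
  exact <- n <= 20L && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = exact, correct = TRUE)
  )
  tibble::tibble(statistic = unname(ht$statistic),
                 p_value = min(ht$p.value, 1),
                 exact = exact)
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Two-sided one-sample signed-rank test of the paired differences against
#' zero. Zero differences are dropped before ranking (the classic Wilcoxon
#' convention). The exact distribution is used when the number of nonzero
#' differences is at most 25 and their absolute values are untied; otherwise
#' the tie-corrected normal approximation with continuity correction.
#'
#' @param diffs Numeric vector of paired differences (n >= 1).
#' @return Tibble with `statistic` (V, sum of positive ranks), `p_value`,
#'   `exact`, `degenerate` (TRUE when all differences are zero, in which case
#'   p = 1).
#' @export
signed_rank <- function(diffs) {
  if (!length(diffs)) stop("need at least one pair", call. = FALSE)
  if (anyNA(diffs)) stop("missing differences not allowed", call. = FALSE)
  nz <- diffs[diffs != 0]
  if (!length(nz)) {
    return(tibble::tibble(statistic = NA_real_, p_value = 1,
                          exact = NA, degenerate = TRUE))
  }
  ties <- anyDuplicated(abs(nz)) > 0L
  exact <- length(nz) <= 25L && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(nz, mu = 0, exact = exact, correct = TRUE)
  )
  tibble::tibble(statistic = unname(ht$statistic),
                 p_value = min(ht$p.value, 1),
                 exact = exact, degenerate = FALSE)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR adjustment; adjusted values are clipped at 1 and returned in
#' the input order.
#'
#' @param p Numeric vector of raw p values in `[0, 1]`.
#' @return Numeric vector of adjusted p values, same length and order.
#' @examples
#' fdr_adjust(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
fdr_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    stop("p values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Univariate scanner / voltage comparison of feature values
#'
#' For each feature and each representative reconstruction setting, compares
#' feature values between the two levels of a grouping variable (scanner
#' model or tube voltage) with the Wilcoxon-Mann-Whitney test, then adjusts
#' all p values of the batch with [fdr_adjust()].
#'
#' @param table A [feature_table()].
#' @param grouping `"scanner"` or `"tube_voltage"`; must have exactly two
#'   levels among the patients present.
#' @param settings Representative settings at which the comparison is run
#'   (default FBP and IR60, the middle of the investigated blending range).
#' @return Tibble with `feature`, `comparison` (e.g. `"scanner@FBP"`),
#'   `statistic`, `p_raw`, `p_fdr`.
#' @export
univariate_group_tests <- function(table, grouping = c("scanner", "tube_voltage"),
                                   settings = c("FBP", "IR60")) {
  stopifnot(inherits(table, "feature_table"))
  grouping <- match.arg(grouping)
  unknown <- setdiff(settings, table$design$settings)
  if (length(unknown)) {
    stop("unknown setting label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  g <- table$patients[[grouping]]
  levels <- sort(unique(as.character(g)))
  if (length(levels) != 2L) {
    stop("grouping variable must have exactly 2 levels", call. = FALSE)
  }
  ids_a <- table$patients$patient_id[as.character(g) == levels[[1L]]]
  grid <- tidyr::expand_grid(feature = table$features$name, setting = settings)
  one <- function(feature, setting) {
    v <- table$values[table$values$feature == feature &
                        table$values$setting == setting, ]
    a <- v$value[v$patient_id %in% ids_a]
    b <- v$value[!v$patient_id %in% ids_a]
    res <- mann_whitney(a, b)
    tibble::tibble(feature = feature,
                   comparison = paste0(grouping, "@", setting),
                   statistic = res$statistic, p_raw = res$p_value)
  }
  out <- purrr::pmap_dfr(grid, one)
  out$p_fdr <- fdr_adjust(out$p_raw)
  out
}

#' Pairwise reconstruction-algorithm sensitivity analysis
#'
#' For every unordered pair of reconstruction settings, runs the Wilcoxon
#' signed-rank test of each feature's paired differences, FDR-adjusts the p
#' values across features within the pair, and counts the features with
#' adjusted p below `alpha` — the data behind a significance heatmap.
#'
#' @param table A [feature_table()].
#' @param alpha Significance level on the FDR-adjusted p (default 0.05).
#' @param image_type Optional filter (`"original"`, `"wavelet"`, `"log"`).
#'   When `"original"`, shape features are excluded (their values are setting
#'   invariant by construction under a shared segmentation).
#' @param settings Settings to compare (default all in the design).
#' @return Symmetric integer matrix (settings x settings, zero diagonal) of
#'   significant-feature counts.
#' @export
pairwise_algorithm_counts <- function(table, alpha = 0.05, image_type = NULL,
                                      settings = table$design$settings) {
  stopifnot(inherits(table, "feature_table"))
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)
  if (length(settings) < 2L) stop("need at least 2 settings", call. = FALSE)
  feats <- table$features
  if (!is.null(image_type)) {
    feats <- feats[feats$image_type == image_type, ]
    if (image_type == "original") {
      feats <- feats[feats$category != "shape", ]
    }
  }
  if (!nrow(feats)) stop("no features left after filtering", call. = FALSE)
  counts <- matrix(0L, length(settings), length(settings),
                   dimnames = list(settings, settings))
  pairs <- utils::combn(settings, 2L, simplify = FALSE)
  for (pr in pairs) {
    p_raw <- purrr::map_dbl(feats$name, function(f) {
      m <- feature_matrix(table, f, pr)
      signed_rank(m[, 1L] - m[, 2L])$p_value
    })
    k <- sum(fdr_adjust(p_raw) < alpha)
    counts[pr[[1L]], pr[[2L]]] <- k
    counts[pr[[2L]], pr[[1L]]] <- k
  }
  counts
}

#' Baseline characteristics comparison between two patient groups
#'
#' Mirrors a study's "Table 1": per covariate, compares the two levels of a
#' grouping variable using the chi-square test (categorical, all expected
#' cell counts >= 5), the Fisher exact test (categorical otherwise) or the
#' Wilcoxon-Mann-Whitney test (continuous). Missing values are dropped per
#' variable and counted.
#'
#' @param patients Patient metadata tibble (as in `table$patients`).
#' @param grouping `"scanner"` or `"tube_voltage"` (two levels required).
#' @param variables Covariates to compare; default all columns other than
#'   `patient_id` and the grouping variable.
#' @return Tibble with `variable`, `test` (`"chisq"`, `"fisher"`,
#'   `"mann_whitney"`), `p_value`, `n_missing`.
#' @export
baseline_comparison <- function(patients, grouping = c("scanner", "tube_voltage"),
                                variables = NULL) {
  grouping <- match.arg(grouping)
  g <- as.character(patients[[grouping]])
  levels <- sort(unique(g))
  if (length(levels) != 2L) {
    stop("grouping variable must have exactly 2 levels", call. = FALSE)
  }
  if (is.null(variables)) {
    variables <- setdiff(names(patients), c("patient_id", grouping))
  }
  one <- function(v) {
    x <- patients[[v]]
    keep <- !is.na(x)
    n_missing <- sum(!keep)
    x <- x[keep]; gg <- g[keep]
    if (is.numeric(x)) {
      p <- suppressWarnings(
        stats::wilcox.test(x[gg == levels[[1L]]], x[gg == levels[[2L]]])$p.value
      )
      test <- "mann_whitney"
    } else {
      tab <- table(factor(x), factor(gg))
      expected <- suppressWarnings(stats::chisq.test(tab)$expected)
      if (all(expected >= 5)) {
        p <- suppressWarnings(stats::chisq.test(tab)$p.value)
        test <- "chisq"
      } else {
        p <- tryCatch(
          stats::fisher.test(tab, workspace = 2e6)$p.value,
          error = function(e) {
            stats::fisher.test(tab, simulate.p.value = TRUE, B = 1e4)$p.value
          }
        )
        test <- "fisher"
      }
    }
    tibble::tibble(variable = v, test = test, p_value = min(p, 1),
                   n_missing = n_missing)
  }
  purrr::map_dfr(variables, one)
}
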