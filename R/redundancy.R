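#' Spearman correlation matrix of features at one setting
#'
#' Rank correlation (average ranks for ties) between features, computed from
#' the patient-by-feature value matrix at a single reconstruction setting.
#' Constant features have undefined correlations and are excluded with a
#' warning.
#'
#' @param table A [feature_table()].
#' @param setting Setting label at which feature values are taken (default
#'   the design's reference).
#' @param features Features to correlate (default all; >= 2 required after
#'   exclusions).
#' @return Symmetric numeric matrix of Spearman rho with unit diagonal.
#' @export
spearman_matrix <- function(table, setting = table$design$reference,
                            features = table$features$name) {
  stopifnot(inherits(table, "feature_table"))
  if (!setting %in% table$design$settings) {
    stop("unknown setting: ", setting, call. = FALSE)
  }
  v <- table$values[table$values$setting == setting &
                      table$values$feature %in% features, ]
  wide <- tidyr::pivot_wider(v[c("patient_id", "feature", "value")],
                             names_from = "feature", values_from = "value")
  m <- as.matrix(wide[setdiff(names(wide), "patient_id")])
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3L) stop("need at least 3 patients", call. = FALSE)
  const <- apply(m, 2L, function(col) stats::sd(col) == 0)
  if (any(const)) {
    warning("constant feature(s) excluded: ",
            paste(colnames(m)[const], collapse = ", "), call. = FALSE)
    m <- m[, !const, drop = FALSE]
  }
  if (ncol(m) < 2L) stop("need at least 2 non-constant features", call. = FALSE)
  rho <- stats::cor(m, method = "spearman")
  diag(rho) <- 1
  rho
}

#' Cluster features under a minimum intra-cluster correlation criterion
#'
#' Complete-linkage agglomerative clustering on the distance `1 - |rho|`,
#' with the tree cut at height `1 - threshold`. Complete linkage makes the
#' merge height the maximum within-cluster distance, so the cut provably
#' guarantees that every pair of features inside a cluster satisfies
#' `|rho| >= threshold` — the stated redundancy criterion. The guarantee is
#' nevertheless audited on the output, not assumed. Features are ordered
#' lexicographically by name before clustering so linkage ties break
#' deterministically.
#'
#' @param rho Symmetric Spearman correlation matrix (e.g. from
#'   [spearman_matrix()]).
#' @param threshold Minimum absolute intra-cluster correlation in (0, 1]
#'   (default 0.75).
#' @return Tibble with `feature`, `cluster` (integer id), `representative`
#'   (TRUE for the cluster member with the highest median absolute
#'   correlation to its cluster mates).
#' @export
cluster_features <- function(rho, threshold = 0.75) {
  if (is.null(dim(rho)) || nrow(rho) == 0L) {
    stop("empty correlation matrix", call. = FALSE)
  }
  if (threshold <= 0 || threshold > 1) {
    stop("`threshold` must be in (0, 1]", call. = FALSE)
  }
  ord <- order(rownames(rho))
  rho <- rho[ord, ord, drop = FALSE]
  d <- 1 - abs(rho)
  if (nrow(rho) == 1L) {
    return(tibble::tibble(feature = rownames(rho), cluster = 1L,
                          representative = TRUE))
  }
  hc <- stats::hclust(stats::as.dist(d), method = "complete")
  cl <- stats::cutree(hc, h = 1 - threshold)
  audit <- vapply(split(names(cl), cl), function(members) {
    if (length(members) < 2L) return(TRUE)
    sub <- abs(rho[members, members])
    min(sub[upper.tri(sub)]) >= threshold
  }, logical(1L))
  stopifnot("intra-cluster correlation audit failed" = all(audit))
  rep_flag <- logical(length(cl))
  names(rep_flag) <- names(cl)
  for (members in split(names(cl), cl)) {
    if (length(members) == 1L) {
      rep_flag[members] <- TRUE
    } else {
      med <- vapply(members, function(f) {
        stats::median(abs(rho[f, setdiff(members, f)]))
      }, numeric(1L))
      rep_flag[members[which.max(med)]] <- TRUE
    }
  }
  tibble::tibble(feature = names(cl), cluster = as.integer(cl),
                 representative = unname(rep_flag))
}
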