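#' Linear mixed model with a random patient intercept, by profiled REML
#'
#' Per feature, fits
#' \deqn{y_{ij} = \beta_0 + \beta_{setting(j)} + \beta_{scanner(i)} +
#'   \beta_{voltage(i)} + \beta_v \, volume_i + b_i + e_{ij}}
#' with \eqn{b_i \sim N(0, \sigma_s^2)} (patient random intercept) and
#' \eqn{e_{ij} \sim N(0, \sigma_e^2)}. The reconstruction setting enters as a
#' categorical factor against the design's reference level, so one
#' coefficient and p value per non-reference blending level measures the
#' systematic shift relative to the reference.
#'
#' Estimation profiles the REML criterion over the single variance ratio
#' \eqn{\lambda = \sigma_s^2/\sigma_e^2} (one-dimensional optimization, with
#' a closed-form generalized-least-squares step per candidate ratio).
#' Inference uses t statistics with the between-within degrees-of-freedom
#' convention: within-patient terms (the setting contrasts) get
#' `n_obs - n_patients - n_within_terms` df, between-patient terms (scanner,
#' voltage, volume, intercept) get `n_patients - n_between_terms - 1` df.
#'
#' Features flagged `is_volume_like` (e.g. the segmented voxel volume itself)
#' automatically drop the tumour-volume covariate.
#'
#' @param table A [feature_table()].
#' @param feature Feature name.
#' @param settings Settings included in the model (default all in design).
#' @param reference Reference setting (default the design's).
#' @param include_volume Adjust for tumour volume (default TRUE; forced off
#'   for volume-like features).
#' @param log_volume Enter volume as log(cm3) instead of raw cm3.
#' @param include_scanner,include_voltage Include the scanner / tube-voltage
#'   fixed effects (default TRUE; silently dropped when only one level is
#'   present in the data).
#' @return An object of class `feature_mm`; see [tidy.feature_mm()] and
#'   [glance.feature_mm()] for tabular views. Key elements: `terms` (tibble
#'   of estimates, standard errors, df, p values), `var_subject`,
#'   `var_residual`, `n_obs`, `n_subjects`, `converged`.
#' @export
fit_feature_mixed_model <- function(table, feature,
                                    settings = table$design$settings,
                                    reference = table$design$reference,
                                    include_volume = TRUE,
                                    log_volume = FALSE,
                                    include_scanner = TRUE,
                                    include_voltage = TRUE) {
  stopifnot(inherits(table, "feature_table"))
  if (!reference %in% settings) {
    stop("reference setting must be among the modelled settings", call. = FALSE)
  }
  d <- feature_long(table, feature, settings)
  d <- d[stats::complete.cases(d[c("value", "setting", "patient_id")]), ]
  if (length(unique(d$setting)) < 2L) {
    stop("need at least 2 settings with data", call. = FALSE)
  }
  if (length(unique(d$patient_id)) < 3L) {
    stop("need at least 3 patients", call. = FALSE)
  }
  fdesc <- table$features[table$features$name == feature, ]
  if (nrow(fdesc) && isTRUE(fdesc$is_volume_like)) include_volume <- FALSE

  setting <- stats::relevel(factor(d$setting, levels = settings), ref = reference)
  X <- stats::model.matrix(~setting)
  within_terms <- colnames(X)[-1L]
  between <- list()
  if (include_scanner) {
    sc <- factor(as.character(d$scanner))
    if (nlevels(sc) > 1L) between$scanner <- sc
  }
  if (include_voltage) {
    vo <- factor(as.character(d$tube_voltage))
    if (nlevels(vo) > 1L) between$voltage <- vo
  }
  if (include_volume) {
    vol <- d$tumour_volume_cm3
    if (log_volume) vol <- log(vol)
    if (stats::sd(vol) > 0) between$volume <- vol
  }
  for (nm in names(between)) {
    v <- between[[nm]]
    if (is.factor(v)) {
      mm <- stats::model.matrix(~v)[, -1L, drop = FALSE]
      colnames(mm) <- paste0(nm, levels(v)[-1L])
      X <- cbind(X, mm)
    } else {
      X <- cbind(X, matrix(v, ncol = 1L, dimnames = list(NULL, nm)))
    }
  }
  between_terms <- setdiff(colnames(X), c("(Intercept)", within_terms))

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1L, ncol(X))]]
    stop("rank-deficient design; collinear term(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  fit <- reml_random_intercept(d$value, X, factor(d$patient_id))

  term_type <- ifelse(colnames(X) %in% within_terms, "within", "between")
  df <- ifelse(term_type == "within",
               fit$n_obs - fit$n_subjects - length(within_terms),
               fit$n_subjects - length(between_terms) - 1L)
  est <- fit$beta
  se <- fit$se
  tstat <- ifelse(se > 0, est / se, ifelse(abs(est) < 1e-10, 0, Inf))
  pval <- ifelse(is.finite(tstat), 2 * stats::pt(-abs(tstat), df),
                 0)
  pval[se == 0 & abs(est) < 1e-10] <- 1
  terms <- tibble::tibble(
    term = colnames(X),
    setting = ifelse(term_type == "within",
                     sub("^setting", "", colnames(X)), NA_character_),
    type = term_type,
    estimate = unname(est), std_error = unname(se), df = df,
    statistic = unname(tstat), p_value = unname(pval)
  )
  structure(
    list(feature = feature, terms = terms, reference = reference,
         settings = settings,
         var_subject = fit$var_subject, var_residual = fit$var_residual,
         lambda = fit$lambda, n_obs = fit$n_obs, n_subjects = fit$n_subjects,
         converged = fit$converged),
    class = "feature_mm"
  )
}

# Profiled-REML engine for a single random intercept.
# V = sigma_e^2 (I + lambda Z Z'); block structure over subjects gives
# closed-form V^{-1} sweeps via per-subject sums, so each candidate lambda
# costs O(N p^2).
#' @noRd
reml_random_intercept <- function(y, X, subject) {
  N <- length(y); p <- ncol(X)
  sub <- as.integer(subject)
  n_subj <- nlevels(subject)
  ni <- tabulate(sub, n_subj)
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  yty <- sum(y^2)
  X1 <- rowsum(X, sub)                      # per-subject column sums
  y1 <- rowsum(y, sub)[, 1L]

  gls <- function(lambda) {
    ci <- lambda / (1 + lambda * ni)
    A <- XtX - crossprod(X1 * sqrt(ci))
    b <- Xty - crossprod(X1, ci * y1)
    R <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(R)) return(NULL)
    beta <- backsolve(R, forwardsolve(t(R), b))
    yVy <- yty - sum(ci * y1^2)
    rss <- max(yVy - sum(b * beta), 0)
    list(beta = drop(beta), A = A, R = R, rss = rss,
         logdetA = 2 * sum(log(diag(R))),
         logdetV = sum(log1p(lambda * ni)))
  }
  scale_y <- mean((y - mean(y))^2)
  eps <- 1e-12 * (scale_y + 1e-300) * N

  # within-subject residual SS from the fixed-effects (within-centred) fit:
  # an exact within-subject fit means the residual variance is genuinely 0,
  # even though the profiled criterion can only approach lambda -> Inf
  yc <- y - (y1 / ni)[sub]
  Xc <- X - (X1 / ni)[sub, , drop = FALSE]
  qrw <- qr(Xc)
  rss_within <- sum(qr.resid(qrw, yc)^2)
  eps_within <- 1e-10 * (scale_y + 1e-300) * N

  crit <- function(lambda) {
    g <- gls(lambda)
    if (is.null(g)) return(Inf)
    (N - p) * log(max(g$rss, eps)) + g$logdetV + g$logdetA
  }

  converged <- TRUE
  opt <- tryCatch(
    stats::optimize(function(t) crit(exp(t)), interval = c(-15, 15)),
    error = function(e) NULL
  )
  if (is.null(opt)) {
    lambda <- 0
    converged <- FALSE
  } else {
    lambda <- exp(opt$minimum)
    if (crit(0) <= opt$objective) lambda <- 0
  }
  g <- gls(lambda)
  if (is.null(g)) {                        # fall back to ordinary regression
    lambda <- 0
    g <- gls(0)
    converged <- FALSE
  }
  var_residual <- g$rss / (N - p)
  degenerate <- g$rss <= eps || rss_within <= eps_within
  covb <- var_residual * chol2inv(g$R)
  var_subject <- lambda * var_residual
  if (degenerate) {
    var_residual <- 0
  }
  if (degenerate && lambda > 0) {
    # recover the between-subject spread from the subject means of residuals
    res <- y - drop(X %*% g$beta)
    mres <- rowsum(res, sub)[, 1L] / ni
    var_subject <- if (n_subj > 1) stats::var(mres) else 0
  }
  list(beta = stats::setNames(g$beta, colnames(X)),
       se = sqrt(pmax(diag(covb), 0)),
       var_subject = var_subject, var_residual = var_residual,
       lambda = lambda, n_obs = N, n_subjects = n_subj,
       converged = converged)
}

#' @export
print.feature_mm <- function(x, ...) {
  cat("<feature_mm> ", x$feature, ": ", x$n_obs, " obs / ", x$n_subjects,
      " patients; var_subject = ", signif(x$var_subject, 4),
      ", var_residual = ", signif(x$var_residual, 4),
      if (!x$converged) " [NOT CONVERGED]", "\n", sep = "")
  print(x$terms)
  invisible(x)
}

#' Tidy a per-feature mixed-model fit
#'
#' @param x A `feature_mm` object.
#' @param ... Unused.
#' @return Tibble with one row per fixed-effect term: `feature`, `term`,
#'   `setting` (the blending level for setting contrasts, NA otherwise),
#'   `type` (within/between), `estimate`, `std_error`, `df`, `statistic`,
#'   `p_value`.
#' @method tidy feature_mm
#' @export
tidy.feature_mm <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(feature = x$feature), x$terms)
}

#' One-row summary of a per-feature mixed-model fit
#'
#' @param x A `feature_mm` object.
#' @param ... Unused.
#' @return Tibble with `feature`, `var_subject`, `var_residual`, `n_obs`,
#'   `n_subjects`, `converged`.
#' @method glance feature_mm
#' @export
glance.feature_mm <- function(x, ...) {
  tibble::tibble(feature = x$feature, var_subject = x$var_subject,
                 var_residual = x$var_residual, n_obs = x$n_obs,
                 n_subjects = x$n_subjects, converged = x$converged)
}

#' Fit the mixed model to every feature and FDR-adjust per term family
#'
#' Runs [fit_feature_mixed_model()] across all features of a table. P values
#' are Benjamini-Hochberg adjusted within term families across features —
#' each setting contrast's p values together (one family per blending
#' level), all scanner p values together, and so on — so every reported
#' column of adjusted p values is corrected over the features it compares.
#'
#' @inheritParams fit_feature_mixed_model
#' @param features Features to fit (default all in the table).
#' @return A list of class `mm_batch` with `terms` (tidy tibble across
#'   features with a `p_fdr` column), `fits` (named list of `feature_mm`),
#'   and `failed` (tibble of features whose fit errored, with messages).
#' @export
batch_mixed_models <- function(table, settings = table$design$settings,
                               reference = table$design$reference,
                               features = table$features$name,
                               include_volume = TRUE, log_volume = FALSE) {
  stopifnot(inherits(table, "feature_table"))
  fits <- list()
  failed <- list()
  for (f in features) {
    res <- tryCatch(
      fit_feature_mixed_model(table, f, settings = settings,
                              reference = reference,
                              include_volume = include_volume,
                              log_volume = log_volume),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failed[[f]] <- conditionMessage(res)
    } else {
      fits[[f]] <- res
    }
  }
  terms <- purrr::map_dfr(fits, tidy)
  if (nrow(terms)) {
    terms$family <- dplyr::case_when(
      terms$type == "within" ~ "setting",
      grepl("^scanner", terms$term) ~ "scanner",
      grepl("^voltage", terms$term) ~ "voltage",
      terms$term == "volume" ~ "volume",
      TRUE ~ "intercept"
    )
    terms <- terms |>
      dplyr::group_by(.data$family, .data$setting) |>
      dplyr::mutate(p_fdr = fdr_adjust(.data$p_value)) |>
      dplyr::ungroup()
    terms$p_fdr[terms$family == "intercept"] <- NA_real_
  }
  structure(
    list(terms = terms, fits = fits,
         failed = tibble::tibble(feature = names(failed),
                                 error = unlist(unname(failed), use.names = FALSE))),
    class = "mm_batch"
  )
}

#' @export
print.mm_batch <- function(x, ...) {
  cat("<mm_batch> ", length(x$fits), " fitted features, ",
      nrow(x$failed), " failed\n", sep = "")
  invisible(x)
}

#' FDR-adjusted setting-contrast p values from a batch of mixed models
#'
#' Convenience extractor: one row per (feature, non-reference setting) with
#' the contrast's estimate and FDR-adjusted p value — the input to the
#' four-group classification.
#'
#' @param batch An `mm_batch` from [batch_mixed_models()].
#' @return Tibble with `feature`, `setting`, `estimate`, `p_value`, `p_fdr`.
#' @export
setting_contrasts <- function(batch) {
  stopifnot(inherits(batch, "mm_batch"))
  batch$terms |>
    dplyr::filter(.data$type == "within") |>
    dplyr::select("feature", "setting", "estimate", "p_value", "p_fdr")
}
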