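#' Configuration for the synthetic feature-table generator
#'
#' Describes a simulated study: patients split over two scanner models and
#' two tube voltages, a reconstruction design, and features planted in the
#' four reproducibility groups. The generative model mirrors the analysis
#' model:
#' \deqn{y_{ijf} = \mu_f + b_{if} + \beta_f(j) + s_f\,scanner_i +
#'   v_f\,voltage_i + w_f\,volume_i + \gamma_{ijf} + e_{ijf}}
#' with patient intercepts \eqn{b_{if} \sim N(0, \sigma_s^2)}, a
#' patient-by-setting random interaction \eqn{\gamma_{ijf}} (zero except for
#' planted group-4 features) and residual noise \eqn{e_{ijf}}.
#'
#' Group-planting regimes (effect sizes expressed relative to the
#' between-patient SD `subject_sd`):
#' * group 1 — a consistent but small linear-in-blending-percent trend,
#'   `|beta|` up to `beta_max["group1"]` (default 0.3), small residual noise:
#'   high concordance, significant trend.
#' * group 2 — no trend, small residual noise: high concordance,
#'   non-significant.
#' * group 3 — a large linear trend, `beta_max["group3"]` (default 2.0): low
#'   concordance, significant.
#' * group 4 — no trend but a large patient-by-setting interaction
#'   (`interaction_sd["group4"]`, default 1.5): low concordance,
#'   non-significant.
#'
#' The configuration is validated against a moment approximation of the
#' expected OCCC; a parameter set whose predicted concordance contradicts its
#' planted group (e.g. group 2 with a huge residual) is rejected.
#'
#' @param n_patients Number of patients (default 103).
#' @param design A [recon_design()] (default: six blending levels 0-80%).
#' @param n_features Named integer vector: features per planted group.
#' @param n_shape Number of shape features (identical across settings under a
#'   shared segmentation; the first is the volume-like
#'   `original_shape_VoxelVolume`).
#' @param n_redundant_pairs Extra feature pairs that are exact monotone
#'   transforms of a base feature (for redundancy-clustering tests).
#' @param subject_sd Between-patient SD (the scale unit).
#' @param residual_sd,beta_max,interaction_sd Named numeric vectors (per
#'   group, as multiples of `subject_sd`).
#' @param scanner_effect_sd,voltage_effect_sd SD of the per-feature scanner /
#'   voltage shifts (between-patient effects).
#' @param volume_slope_sd SD of the per-feature tumour-volume slope (per
#'   cm3).
#' @param volume_meanlog,volume_sdlog,volume_range Log-normal tumour-volume
#'   distribution, truncated to `volume_range` cm3 (default `[5, 200]`, the
#'   usual inclusion window).
#' @param scanner_split,voltage_split Fraction of patients on the first
#'   scanner model / first voltage.
#' @param seed Integer seed; the generator is bit-reproducible given the
#'   configuration.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 103L,
                             design = recon_design(),
                             n_features = c(group1 = 25L, group2 = 25L,
                                            group3 = 25L, group4 = 25L),
                             n_shape = 4L,
                             n_redundant_pairs = 0L,
                             subject_sd = 1,
                             residual_sd = c(group1 = 0.1, group2 = 0.1,
                                             group3 = 0.1, group4 = 0.1),
                             beta_max = c(group1 = 0.3, group2 = 0,
                                          group3 = 2.0, group4 = 0),
                             interaction_sd = c(group1 = 0, group2 = 0,
                                                group3 = 0, group4 = 1.5),
                             scanner_effect_sd = 0.2,
                             voltage_effect_sd = 0.2,
                             volume_slope_sd = 0.003,
                             volume_meanlog = log(30), volume_sdlog = 0.6,
                             volume_range = c(5, 200),
                             scanner_split = 0.5, voltage_split = 0.5,
                             seed = 1L) {
  groups <- paste0("group", 1:4)
  cfg <- list(n_patients = as.integer(n_patients), design = design,
              n_features = n_features[groups], n_shape = as.integer(n_shape),
              n_redundant_pairs = as.integer(n_redundant_pairs),
              subject_sd = subject_sd,
              residual_sd = residual_sd[groups], beta_max = beta_max[groups],
              interaction_sd = interaction_sd[groups],
              scanner_effect_sd = scanner_effect_sd,
              voltage_effect_sd = voltage_effect_sd,
              volume_slope_sd = volume_slope_sd,
              volume_meanlog = volume_meanlog, volume_sdlog = volume_sdlog,
              volume_range = volume_range,
              scanner_split = scanner_split, voltage_split = voltage_split,
              seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

#' @noRd
validate_synthetic_config <- function(cfg) {
  stopifnot(inherits(cfg, "recon_design") || inherits(cfg$design, "recon_design"))
  if (cfg$n_patients < 4L) stop("need at least 4 patients", call. = FALSE)
  if (anyNA(cfg$n_features) || any(cfg$n_features < 0L)) {
    stop("n_features must give a nonnegative count per group", call. = FALSE)
  }
  if (cfg$subject_sd <= 0) stop("subject_sd must be positive", call. = FALSE)
  if (cfg$volume_range[[1L]] <= 0 || diff(cfg$volume_range) <= 0) {
    stop("invalid volume_range", call. = FALSE)
  }
  # moment approximation of the expected OCCC for each planted regime
  pred <- vapply(paste0("group", 1:4), function(g) {
    predicted_occc(cfg$design, cfg$subject_sd,
                   cfg$beta_max[[g]] * cfg$subject_sd,
                   cfg$residual_sd[[g]] * cfg$subject_sd,
                   cfg$interaction_sd[[g]] * cfg$subject_sd)
  }, numeric(1L))
  high <- c("group1", "group2"); low <- c("group3", "group4")
  bad_high <- high[cfg$n_features[high] > 0L & pred[high] < 0.87]
  bad_low <- low[cfg$n_features[low] > 0L & pred[low] > 0.83]
  if (length(bad_high) || length(bad_low)) {
    stop("contradictory preset: predicted OCCC inconsistent with planted ",
         "group for ", paste(c(bad_high, bad_low), collapse = ", "),
         call. = FALSE)
  }
  if (cfg$beta_max[["group2"]] != 0 || cfg$beta_max[["group4"]] != 0) {
    stop("groups 2 and 4 must have no systematic trend (beta_max = 0)",
         call. = FALSE)
  }
  if (cfg$beta_max[["group1"]] == 0 || cfg$beta_max[["group3"]] == 0) {
    stop("groups 1 and 3 require a nonzero trend", call. = FALSE)
  }
  invisible(cfg)
}

# Expected OCCC under the generative model, from population moments:
# column covariances sigma_s^2, column variances sigma_s^2 + sigma_e^2 +
# sigma_i^2, mean differences from the linear-in-percent trend.
#' @noRd
predicted_occc <- function(design, subject_sd, beta_max, residual_sd,
                           interaction_sd) {
  beta <- linear_trend(design, beta_max)
  J <- length(beta)
  var_col <- subject_sd^2 + residual_sd^2 + interaction_sd^2
  mean_diff2 <- sum(outer(beta, beta, "-")[upper.tri(diag(J))]^2)
  (J * (J - 1) * subject_sd^2) / ((J - 1) * J * var_col + mean_diff2)
}

# Linear-in-blending-percent setting effects, zero at the reference,
# max |beta| = beta_max.
#' @noRd
linear_trend <- function(design, beta_max) {
  pct <- design$blending_percent
  rel <- pct - pct[[design$reference]]
  if (all(rel == 0) || beta_max == 0) {
    return(stats::setNames(rep(0, length(pct)), names(pct)))
  }
  stats::setNames(beta_max * rel / max(abs(rel)), names(pct))
}

#' Named generator presets
#'
#' @description
#' * `paper_shaped` — 103 patients, six blending levels, a mixture of all
#'   four groups plus shape features: the full-pipeline workout.
#' * `group1` ... `group4` — homogeneous batches of one planted group (for
#'   recovery-rate measurement).
#' * `redundancy` — a small table with exact monotone-transform feature
#'   copies for clustering tests.
#'
#' @param name Preset name.
#' @param seed Integer seed stored in the configuration.
#' @return A [synthetic_config()].
#' @export
synthetic_preset <- function(name = c("paper_shaped", "group1", "group2",
                                      "group3", "group4", "redundancy"),
                             seed = 1L) {
  name <- match.arg(name)
  switch(name,
    paper_shaped = synthetic_config(seed = seed),
    group1 = one_group_config(1L, seed),
    group2 = one_group_config(2L, seed),
    group3 = one_group_config(3L, seed),
    group4 = one_group_config(4L, seed),
    redundancy = synthetic_config(
      n_patients = 40L,
      n_features = c(group1 = 0L, group2 = 6L, group3 = 0L, group4 = 0L),
      n_shape = 0L, n_redundant_pairs = 3L, seed = seed
    )
  )
}

#' @noRd
one_group_config <- function(g, seed) {
  nf <- stats::setNames(rep(0L, 4L), paste0("group", 1:4))
  nf[[g]] <- 25L
  synthetic_config(n_features = nf, n_shape = 0L, seed = seed)
}

#' Simulate a feature table with planted ground truth
#'
#' Draws patients (scanner, voltage, truncated log-normal tumour volume) and
#' feature values from the generative model described in
#' [synthetic_config()], returning the complete [feature_table()] together
#' with the generating parameters of every feature.
#'
#' @param config A [synthetic_config()] (or a preset name for
#'   [synthetic_preset()]).
#' @param seed Optional override of `config$seed`.
#' @return List with `table` (a [feature_table()]) and `truth` (list of
#'   class `synthetic_truth` with tibbles `features` — per-feature
#'   `planted_group`, effect SDs, scanner/voltage/volume effects — and
#'   `betas` — the planted per-setting coefficients, zero at the reference).
#' @export
simulate_feature_table <- function(config = synthetic_config(), seed = NULL) {
  if (is.character(config)) config <- synthetic_preset(config)
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  withr::local_seed(config$seed)

  design <- config$design
  n <- config$n_patients
  J <- length(design$settings)
  patient_id <- sprintf("P%03d", seq_len(n))
  scanner <- ifelse(seq_len(n) <= round(config$scanner_split * n),
                    "DiscoveryCT750HD", "OptimaCT660")
  n100 <- round(config$voltage_split * n)
  voltage <- sample(c(rep("100", n100), rep("120", n - n100)))
  vol <- numeric(0)
  while (length(vol) < n) {
    draw <- stats::rlnorm(n, config$volume_meanlog, config$volume_sdlog)
    vol <- c(vol, draw[draw >= config$volume_range[[1L]] &
                         draw <= config$volume_range[[2L]]])
  }
  vol <- vol[seq_len(n)]
  patients <- tibble::tibble(patient_id = patient_id, scanner = scanner,
                             tube_voltage = voltage, tumour_volume_cm3 = vol)
  sc_ind <- as.numeric(scanner == "OptimaCT660")
  vo_ind <- as.numeric(voltage == "120")

  specs <- feature_specs(config)
  truth_feat <- list(); truth_beta <- list(); values <- list()

  for (k in seq_len(nrow(specs))) {
    sp <- specs[k, ]
    s_eff <- stats::rnorm(1L, 0, config$scanner_effect_sd)
    v_eff <- stats::rnorm(1L, 0, config$voltage_effect_sd)
    w_eff <- stats::rnorm(1L, 0, config$volume_slope_sd)
    mu <- stats::rnorm(1L, 0, 3)
    direction <- sample(c(-1, 1), 1L)
    beta <- direction * linear_trend(design, sp$beta_max)
    subj <- stats::rnorm(n, 0, config$subject_sd)
    base <- mu + subj + s_eff * sc_ind + v_eff * vo_ind + w_eff * vol
    if (sp$constant_across_settings) {
      col <- if (sp$volume_like) vol else base
      y <- matrix(rep(col, J), nrow = n)
      beta[] <- 0
      s_eff <- v_eff <- w_eff <- 0
    } else {
      gamma <- if (sp$interaction_sd > 0) {
        matrix(stats::rnorm(n * J, 0, sp$interaction_sd), n, J)
      } else 0
      eps <- matrix(stats::rnorm(n * J, 0, sp$residual_sd), n, J)
      y <- base + matrix(beta, n, J, byrow = TRUE) + gamma + eps
    }
    values[[k]] <- tibble::tibble(
      patient_id = rep(patient_id, J),
      setting = rep(design$settings, each = n),
      feature = sp$name,
      value = as.vector(y)
    )
    truth_feat[[k]] <- tibble::tibble(
      feature = sp$name, planted_group = sp$group,
      scanner_effect = s_eff, voltage_effect = v_eff, volume_slope = w_eff,
      subject_sd = config$subject_sd,
      residual_sd = sp$residual_sd, interaction_sd = sp$interaction_sd
    )
    truth_beta[[k]] <- tibble::tibble(feature = sp$name,
                                      setting = design$settings,
                                      beta = unname(beta))
  }
  values <- dplyr::bind_rows(values)

  # exact monotone-transform copies of the first base feature, if requested
  if (config$n_redundant_pairs > 0L) {
    base_name <- specs$name[!specs$constant_across_settings][1L]
    base_rows <- values[values$feature == base_name, ]
    extra <- purrr::map_dfr(seq_len(config$n_redundant_pairs), function(i) {
      up <- dplyr::mutate(base_rows,
                          feature = sprintf("original_glcm_RedundantUp%02d", i),
                          value = exp(.data$value / 2) + i)
      down <- dplyr::mutate(base_rows,
                            feature = sprintf("original_glcm_RedundantDown%02d", i),
                            value = -3 * .data$value + i)
      dplyr::bind_rows(up, down)
    })
    values <- dplyr::bind_rows(values, extra)
    red_truth <- tibble::tibble(
      feature = unique(extra$feature),
      planted_group = 2L, scanner_effect = NA_real_,
      voltage_effect = NA_real_, volume_slope = NA_real_,
      subject_sd = config$subject_sd,
      residual_sd = config$residual_sd[["group2"]] * config$subject_sd,
      interaction_sd = 0
    )
    truth_feat <- c(truth_feat, list(red_truth))
  }

  features <- parse_feature_names(unique(values$feature))
  tab <- feature_table(values, patients, features, design)
  truth <- structure(
    list(features = dplyr::bind_rows(truth_feat),
         betas = dplyr::bind_rows(truth_beta),
         config = config),
    class = "synthetic_truth"
  )
  list(table = tab, truth = truth)
}

# Per-feature generating parameters, with Pyradiomics-style name templates
# cycling over image types and categories.
#' @noRd
feature_specs <- function(config) {
  imgs <- c("original", "wavelet-LH", "wavelet-HL", "wavelet-HH", "wavelet-LL",
            "log-sigma-1-0-mm", "log-sigma-2-5-mm")
  cats <- c("firstorder", "glcm", "glrlm", "glszm", "ngtdm", "gldm")
  out <- list()
  idx <- 0L
  for (g in 1:4) {
    key <- paste0("group", g)
    ng <- config$n_features[[key]]
    if (ng == 0L) next
    for (i in seq_len(ng)) {
      idx <- idx + 1L
      img <- imgs[(idx - 1L) %% length(imgs) + 1L]
      cat <- cats[(idx - 1L) %% length(cats) + 1L]
      out[[length(out) + 1L]] <- tibble::tibble(
        name = sprintf("%s_%s_Sim%03d", img, cat, idx),
        group = g,
        beta_max = config$beta_max[[key]] * config$subject_sd,
        residual_sd = config$residual_sd[[key]] * config$subject_sd,
        interaction_sd = config$interaction_sd[[key]] * config$subject_sd,
        constant_across_settings = FALSE, volume_like = FALSE
      )
    }
  }
  if (config$n_shape > 0L) {
    shape_names <- c("original_shape_VoxelVolume",
                     sprintf("original_shape_Sim%02d",
                             seq_len(max(config$n_shape - 1L, 0L))))
    shape_names <- shape_names[seq_len(config$n_shape)]
    for (j in seq_along(shape_names)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        name = shape_names[[j]], group = 2L, beta_max = 0,
        residual_sd = 0, interaction_sd = 0,
        constant_across_settings = TRUE, volume_like = j == 1L
      )
    }
  }
  dplyr::bind_rows(out)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config> ", x$n_patients, " patients x ",
      length(x$design$settings), " settings; features per group: ",
      paste(x$n_features, collapse = "/"), "; seed ", x$seed, "\n", sep = "")
  invisible(x)
}
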