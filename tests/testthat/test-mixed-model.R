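test_that("REML fit matches lme4 on simulated data", {
  skip_if_not_installed("lme4")
  sim <- simulate_feature_table(
    synthetic_config(n_patients = 40L,
                     n_features = c(group1 = 2L, group2 = 1L,
                                    group3 = 1L, group4 = 1L),
                     n_shape = 0L, seed = 77))
  for (f in sim$table$features$name[1:3]) {
    fit <- fit_feature_mixed_model(sim$table, f)
    d <- dplyr::inner_join(
      sim$table$values[sim$table$values$feature == f, ],
      sim$table$patients, by = "patient_id")
    d$setting <- stats::relevel(factor(d$setting), "FBP")
    lf <- lme4::lmer(value ~ setting + scanner + tube_voltage +
                       tumour_volume_cm3 + (1 | patient_id),
                     data = d, REML = TRUE)
    expect_equal(unname(fit$terms$estimate), unname(lme4::fixef(lf)),
                 tolerance = 1e-7)
    vc <- as.data.frame(lme4::VarCorr(lf))$vcov
    expect_equal(fit$var_subject, vc[1], tolerance = 1e-5)
    expect_equal(fit$var_residual, vc[2], tolerance = 1e-5)
  }
})

test_that("balanced complete data: setting coefficients are paired mean
           differences vs the reference", {
  sim <- simulate_feature_table(synthetic_preset("group1", seed = 12))
  f <- sim$table$features$name[1]
  fit <- fit_feature_mixed_model(sim$table, f)
  m <- feature_matrix(sim$table, f)
  pd <- colMeans(m[, -1, drop = FALSE] - m[, 1])
  est <- fit$terms$estimate[fit$terms$type == "within"]
  names(est) <- fit$terms$setting[fit$terms$type == "within"]
  expect_equal(est[names(pd)], pd, tolerance = 1e-10)
})

test_that("zero-noise planted shift is recovered exactly; null data give
           zero coefficients and zero residual variance", {
  withr::local_seed(5)
  design <- recon_design()
  n <- 10L
  base <- rnorm(n)
  shifted <- matrix(base, n, 6)
  shifted[, 6] <- shifted[, 6] + 2       # +2 at IR80, no noise
  tab <- make_small_table(list(original_glcm_S = shifted,
                               original_gldm_N = matrix(base, n, 6)),
                          n = n, design = design)
  fit <- fit_feature_mixed_model(tab, "original_glcm_S")
  est <- fit$terms$estimate[fit$terms$type == "within"]
  names(est) <- fit$terms$setting[fit$terms$type == "within"]
  expect_equal(unname(est["IR80"]), 2, tolerance = 1e-9)
  expect_equal(unname(est[c("IR20", "IR40", "IR50", "IR60")]), rep(0, 4),
               tolerance = 1e-9)

  null_fit <- fit_feature_mixed_model(tab, "original_gldm_N")
  expect_equal(null_fit$var_residual, 0, tolerance = 1e-8)
  expect_equal(null_fit$terms$estimate[null_fit$terms$type == "within"],
               rep(0, 5), tolerance = 1e-9)
  expect_equal(null_fit$terms$p_value[null_fit$terms$type == "within"],
               rep(1, 5))
})

test_that("fit is invariant to constant shifts and setting label order", {
  sim <- simulate_feature_table(synthetic_preset("group1", seed = 31))
  f <- sim$table$features$name[2]
  fit <- fit_feature_mixed_model(sim$table, f)

  v2 <- sim$table$values
  v2$value[v2$feature == f] <- v2$value[v2$feature == f] + 100
  tab2 <- feature_table(v2, sim$table$patients, sim$table$features,
                        sim$table$design)
  fit2 <- fit_feature_mixed_model(tab2, f)
  within <- fit$terms$type == "within"
  expect_equal(fit2$terms$estimate[within], fit$terms$estimate[within],
               tolerance = 1e-10)
  between <- !within & fit$terms$term != "(Intercept)"
  expect_equal(fit2$terms$estimate[between], fit$terms$estimate[between],
               tolerance = 1e-6)
  expect_equal(fit2$terms$estimate[1] - fit$terms$estimate[1], 100,
               tolerance = 1e-8)

  reordered <- rev(sim$table$design$settings)
  fit3 <- fit_feature_mixed_model(sim$table, f, settings = reordered,
                                  reference = "FBP")
  t1 <- fit$terms[order(fit$terms$term), ]
  t3 <- fit3$terms[order(fit3$terms$term), ]
  expect_equal(t3$estimate, t1$estimate, tolerance = 1e-8)
  expect_equal(t3$p_value, t1$p_value, tolerance = 1e-6)
})

test_that("volume-like features drop the volume covariate; collinearity is a
           named error", {
  sim <- simulate_feature_table(synthetic_preset("paper_shaped", seed = 2))
  fit <- fit_feature_mixed_model(sim$table, "original_shape_VoxelVolume")
  expect_false("volume" %in% fit$terms$term)
  other <- fit_feature_mixed_model(sim$table, sim$table$features$name[1])
  expect_true("volume" %in% other$terms$term)

  # a patient covariate duplicating the scanner indicator is collinear
  tab <- sim$table
  tab$patients$tumour_volume_cm3 <- 5 + as.numeric(tab$patients$scanner ==
                                                     "OptimaCT660")
  expect_error(fit_feature_mixed_model(tab, tab$features$name[1]),
               "collinear")
})

test_that("variance components are nonnegative and REML optimum is locally
           optimal in the profiled criterion", {
  sim <- simulate_feature_table(synthetic_preset("group4", seed = 44))
  f <- sim$table$features$name[1]
  fit <- fit_feature_mixed_model(sim$table, f)
  expect_gte(fit$var_subject, 0)
  expect_gt(fit$var_residual, 0)
  # spot check: perturbing the fitted variance ratio does not improve REML
  d <- dplyr::inner_join(sim$table$values[sim$table$values$feature == f, ],
                         sim$table$patients, by = "patient_id")
  y <- d$value
  X <- stats::model.matrix(~ stats::relevel(factor(d$setting), "FBP"))
  subject <- factor(d$patient_id)
  reml2 <- function(lambda) {
    Z <- stats::model.matrix(~ subject - 1)
    V <- diag(length(y)) + lambda * tcrossprod(Z)
    Vi <- solve(V)
    A <- t(X) %*% Vi %*% X
    beta <- solve(A, t(X) %*% Vi %*% y)
    r <- y - X %*% beta
    rss <- drop(t(r) %*% Vi %*% r)
    (length(y) - ncol(X)) * log(rss) +
      determinant(V)$modulus + determinant(A)$modulus
  }
  lam <- fit$var_subject / fit$var_residual
  f0 <- reml2(lam)
  expect_lte(f0, reml2(lam * 1.25) + 1e-6)
  expect_lte(f0, reml2(lam * 0.8) + 1e-6)
})

test_that("batch fitting FDR-adjusts per term family and reports failures", {
  sim <- simulate_feature_table(
    synthetic_config(n_patients = 25L,
                     n_features = c(group1 = 3L, group2 = 3L,
                                    group3 = 0L, group4 = 0L),
                     n_shape = 0L, seed = 55))
  batch <- batch_mixed_models(sim$table)
  expect_equal(nrow(batch$failed), 0L)
  ctr <- setting_contrasts(batch)
  expect_equal(nrow(ctr), 6L * 5L)
  # family-wise BH: each contrast adjusted across the six features
  for (s in unique(ctr$setting)) {
    rows <- ctr$setting == s
    expect_equal(ctr$p_fdr[rows], fdr_adjust(ctr$p_value[rows]))
  }
  expect_true(all(ctr$p_fdr >= ctr$p_value))

  single <- batch_mixed_models(sim$table, features = sim$table$features$name[1])
  lone <- fit_feature_mixed_model(sim$table, sim$table$features$name[1])
  sctr <- setting_contrasts(single)
  expect_equal(sctr$p_fdr, sctr$p_value)   # m = 1 identity
  expect_equal(sctr$estimate,
               lone$terms$estimate[lone$terms$type == "within"])
})

test_that("tidy and glance expose the fit in broom style", {
  sim <- simulate_feature_table(synthetic_preset("group2", seed = 8))
  fit <- fit_feature_mixed_model(sim$table, sim$table$features$name[1])
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("feature", "term", "estimate", "std_error", "df",
                    "statistic", "p_value") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_true(gl$converged)
  expect_equal(gl$n_obs, gl$n_subjects * 6L)
})
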