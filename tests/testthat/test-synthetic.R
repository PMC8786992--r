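test_that("generation is bit-reproducible given the seed and complete", {
  cfg <- synthetic_config(n_patients = 20L,
                          n_features = c(group1 = 2L, group2 = 2L,
                                         group3 = 2L, group4 = 2L),
                          n_shape = 2L, seed = 5)
  a <- simulate_feature_table(cfg)
  b <- simulate_feature_table(cfg)
  expect_identical(a$table$values, b$table$values)
  expect_identical(a$table$patients, b$table$patients)
  expect_equal(n_missing_cells(a$table), 0L)
  expect_equal(nrow(a$table$patients), 20L)
  expect_equal(nrow(a$table$features), 10L)

  c2 <- simulate_feature_table(cfg, seed = 6)
  expect_false(identical(a$table$values$value, c2$table$values$value))
})

test_that("patients respect the study design: volumes in [5, 200] cm3, two
           scanners, two voltages near a 50/50 split", {
  sim <- simulate_feature_table(synthetic_preset("paper_shaped", seed = 4))
  p <- sim$table$patients
  expect_equal(nrow(p), 103L)
  expect_true(all(p$tumour_volume_cm3 >= 5 & p$tumour_volume_cm3 <= 200))
  expect_equal(sort(unique(p$scanner)), c("DiscoveryCT750HD", "OptimaCT660"))
  expect_equal(sort(unique(p$tube_voltage)), c("100", "120"))
  expect_equal(unname(table(p$tube_voltage)[["100"]]), 52L)
})

test_that("planted truth is internally consistent: zero beta at the
           reference, groups match their generating regime", {
  sim <- simulate_feature_table(synthetic_preset("paper_shaped", seed = 14))
  tr <- sim$truth
  ref_beta <- tr$betas$beta[tr$betas$setting == "FBP"]
  expect_true(all(ref_beta == 0))
  by_group <- dplyr::inner_join(
    dplyr::summarise(dplyr::group_by(tr$betas, feature),
                     max_beta = max(abs(beta))),
    tr$features, by = "feature")
  expect_true(all(by_group$max_beta[by_group$planted_group %in% c(2L, 4L)] == 0))
  g13 <- by_group[by_group$planted_group %in% c(1L, 3L), ]
  expect_true(all(g13$max_beta > 0))
  expect_true(all(by_group$interaction_sd[by_group$planted_group == 4L] > 0))
})

test_that("empirical moments match the planted parameters at large n", {
  cfg <- synthetic_config(n_patients = 1000L,
                          n_features = c(group1 = 1L, group2 = 0L,
                                         group3 = 1L, group4 = 0L),
                          n_shape = 0L, scanner_effect_sd = 0,
                          voltage_effect_sd = 0, volume_slope_sd = 0,
                          seed = 99)
  sim <- simulate_feature_table(cfg)
  f <- sim$table$features$name[1]
  m <- feature_matrix(sim$table, f)
  truth_beta <- sim$truth$betas[sim$truth$betas$feature == f, ]
  observed_shift <- colMeans(m) - mean(m[, "FBP"])
  planted <- setNames(truth_beta$beta, truth_beta$setting)[colnames(m)]
  expect_equal(unname(observed_shift), unname(planted), tolerance = 0.05)
  # between-patient SD close to subject_sd = 1
  expect_equal(sd(rowMeans(m)), 1, tolerance = 0.1)
  # residual SD close to 0.1
  within <- m - rowMeans(m) - matrix(planted - mean(planted),
                                     nrow(m), 6, byrow = TRUE)
  # row-centring absorbs 1/J of the residual variance
  expect_equal(sd(as.vector(within)) * sqrt(6 / 5), 0.1, tolerance = 0.02)
})

test_that("contradictory presets are rejected at validation", {
  expect_error(
    synthetic_config(residual_sd = c(group1 = 0.1, group2 = 3,
                                     group3 = 0.1, group4 = 0.1)),
    "contradictory"
  )
  expect_error(
    synthetic_config(beta_max = c(group1 = 0.3, group2 = 0.5,
                                  group3 = 2, group4 = 0)),
    "no systematic trend"
  )
  expect_error(synthetic_config(n_patients = 2L), "at least 4")
  expect_error(synthetic_preset("nonexistent"))
})

test_that("presets produce the documented shapes", {
  cfg <- synthetic_preset("paper_shaped", seed = 3)
  expect_equal(cfg$n_patients, 103L)
  expect_equal(length(cfg$design$settings), 6L)
  expect_equal(sum(cfg$n_features), 100L)
  g2 <- synthetic_preset("group2", seed = 3)
  expect_equal(unname(g2$n_features), c(0L, 25L, 0L, 0L))
  red <- simulate_feature_table(synthetic_preset("redundancy", seed = 3))
  expect_true(any(grepl("RedundantUp", red$table$features$name)))
})
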