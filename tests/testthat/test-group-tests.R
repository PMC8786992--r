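test_that("Mann-Whitney matches hand enumeration and handles identical groups", {
  res <- mann_whitney(c(1, 2, 3), c(10, 11, 12))
  expect_true(res$exact)
  expect_equal(res$p_value, 0.1)      # U = 0; 2 / C(6,3)
  expect_equal(res$statistic, 0)

  same <- mann_whitney(c(1, 2, 3), c(1.0001, 2.0001, 3.0001))
  expect_gt(same$p_value, 0.6)
  expect_error(mann_whitney(numeric(0), 1:3), "nonempty")
})

test_that("exact Mann-Whitney agrees with the permutation oracle", {
  withr::local_seed(21)
  for (i in 1:40) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    a <- rnorm(na); b <- rnorm(nb, mean = runif(1, -1, 1))
    res <- mann_whitney(a, b)
    expect_true(res$exact)
    expect_equal(res$p_value, mw_enum_p(a, b), tolerance = 1e-12)
  }
})

test_that("signed-rank matches sign-flip enumeration; zeros are dropped", {
  res <- signed_rank(c(1, 2, 3, 4, 5))
  expect_true(res$exact)
  expect_equal(res$p_value, 2 / 32)
  expect_equal(res$statistic, 15)

  degen <- signed_rank(rep(0, 6))
  expect_true(degen$degenerate)
  expect_equal(degen$p_value, 1)

  withr::local_seed(22)
  for (i in 1:40) {
    n <- sample(4:10, 1)
    d <- rnorm(n, mean = runif(1, -0.5, 0.5))
    res <- signed_rank(d)
    expect_true(res$exact)
    expect_equal(res$p_value, sr_enum_p(d), tolerance = 1e-12)
  }
  # zero differences removed before ranking
  expect_equal(signed_rank(c(0, 0, 1, 2, 3))$p_value,
               signed_rank(c(1, 2, 3))$p_value)
})

test_that("BH adjustment reproduces the step-up formula and its properties", {
  expect_equal(fdr_adjust(0.05), 0.05)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  withr::local_seed(30)
  p <- runif(50)
  adj <- fdr_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  perm <- sample(50)
  expect_equal(fdr_adjust(p[perm]), adj[perm])
  # monotone in the ranked raw p values
  ord <- order(p)
  expect_true(all(diff(adj[ord]) >= 0))
})

test_that("univariate scanner/voltage tests run per feature and FDR-adjust", {
  sim <- simulate_feature_table(
    synthetic_config(n_patients = 20L,
                     n_features = c(group1 = 2L, group2 = 2L,
                                    group3 = 0L, group4 = 0L),
                     n_shape = 0L, seed = 9))
  res <- univariate_group_tests(sim$table, "scanner")
  expect_equal(nrow(res), 4L * 2L)     # features x representative settings
  expect_true(all(res$p_fdr >= res$p_raw))
  expect_true(all(startsWith(res$comparison, "scanner@")))
})

test_that("pairwise signed-rank counts: zero for setting-invariant features,
           monotone in blending gap for trend features", {
  withr::local_seed(40)
  flat <- matrix(rep(rnorm(8), 6), 8, 6)
  tab0 <- make_small_table(list(original_glcm_A = flat,
                                original_gldm_B = flat + 1), n = 8L)
  counts0 <- pairwise_algorithm_counts(tab0, image_type = "original")
  expect_true(all(counts0 == 0L))
  expect_equal(counts0, t(counts0))

  sim <- simulate_feature_table(synthetic_preset("group3", seed = 3))
  counts <- pairwise_algorithm_counts(sim$table, settings = sim$table$design$settings)
  expect_equal(counts, t(counts))
  expect_true(all(diag(counts) == 0L))
  # for gaps sharing FBP as lower level, counts do not decrease with the gap
  row_fbp <- counts["FBP", c("IR20", "IR40", "IR50", "IR60", "IR80")]
  expect_true(all(diff(row_fbp) >= 0))

  expect_error(pairwise_algorithm_counts(tab0, alpha = 1.5), "alpha")
})

test_that("baseline comparison picks chi-square, Fisher or Mann-Whitney", {
  patients <- tibble::tibble(
    patient_id = sprintf("p%02d", 1:20),
    scanner = rep(c("A", "B"), each = 10),
    tube_voltage = rep(c("100", "120"), 10),
    tumour_volume_cm3 = rep(c(10, 20), 10),
    histology = rep(c("adeno", "squamous"), 10),   # balanced across scanners
    age = c(rnorm(10, 60), rnorm(10, 60))
  )
  res <- baseline_comparison(patients, "scanner")
  expect_setequal(res$variable,
                  c("tube_voltage", "tumour_volume_cm3", "histology", "age"))
  bal <- res[res$variable == "histology", ]
  expect_equal(bal$test, "chisq")
  expect_equal(bal$p_value, 1)

  # small separated cohort: expected counts below 5 force the Fisher branch
  small <- tibble::tibble(
    patient_id = sprintf("q%02d", 1:10),
    scanner = rep(c("A", "B"), each = 5),
    tube_voltage = rep("100", 10),
    tumour_volume_cm3 = runif(10, 5, 50),
    separated = rep(c("x", "y"), each = 5)
  )
  sep <- baseline_comparison(small, "scanner", variables = "separated")
  expect_equal(sep$test, "fisher")
  # 2x2 table [[5,0],[0,5]]: two-sided hypergeometric mass 2/252
  expect_equal(sep$p_value, 2 / choose(10, 5), tolerance = 1e-12)
  ident <- res[res$variable == "tumour_volume_cm3", ]
  expect_equal(ident$test, "mann_whitney")
  expect_gt(ident$p_value, 0.99)

  expect_error(baseline_comparison(patients[1:10, ], "scanner"), "2 levels")
})
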