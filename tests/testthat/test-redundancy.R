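test_that("Spearman matrix matches the rank-difference formula and handles
           duplicates, monotone transforms and constants", {
  withr::local_seed(90)
  n <- 8L
  x <- rnorm(n)
  vals <- list(
    original_glcm_A = matrix(x, n, 6),
    original_glcm_B = matrix(2 * x, n, 6),            # rho = 1 with A
    original_gldm_C = matrix(-x^3, n, 6),             # rho = -1 with A
    original_glszm_D = matrix(rep(1, n), n, 6)        # constant
  )
  tab <- make_small_table(vals, n = n)
  expect_warning(rho <- spearman_matrix(tab, "FBP"), "constant")
  expect_false("original_glszm_D" %in% rownames(rho))
  expect_equal(rho["original_glcm_A", "original_glcm_B"], 1)
  expect_equal(rho["original_glcm_A", "original_gldm_C"], -1)
  expect_equal(diag(rho), setNames(rep(1, 3), rownames(rho)))

  # hand-evaluated rank-difference case
  tab2 <- make_small_table(list(f1 = matrix(c(1, 2, 3, 4, 5), 5, 6),
                                f2 = matrix(c(1, 3, 2, 5, 4), 5, 6)), n = 5L)
  rho2 <- spearman_matrix(tab2, "FBP")
  expect_equal(rho2["f1", "f2"], 0.8)
})

test_that("complete-linkage clustering guarantees and audits the minimum
           intra-cluster correlation", {
  withr::local_seed(91)
  n <- 30L
  f1 <- rnorm(n)
  vals <- list(
    original_glcm_A = matrix(f1, n, 6),
    original_glcm_B = matrix(2 * f1 + 1, n, 6),
    original_gldm_C = matrix(rnorm(n), n, 6)
  )
  tab <- make_small_table(vals, n = n)
  rho <- spearman_matrix(tab, "FBP")
  expect_lt(abs(rho["original_glcm_A", "original_gldm_C"]), 0.75)
  cl <- cluster_features(rho, 0.75)
  ab <- cl$cluster[cl$feature %in% c("original_glcm_A", "original_glcm_B")]
  expect_equal(ab[1], ab[2])
  expect_length(unique(cl$cluster), 2L)
  expect_equal(sum(cl$representative), 2L)

  # every feature in exactly one cluster
  expect_setequal(cl$feature, rownames(rho))
  expect_equal(anyDuplicated(cl$feature), 0L)
})

test_that("cluster count shrinks as the threshold decreases; threshold 1
           keeps only perfectly rank-correlated features together", {
  withr::local_seed(92)
  m <- matrix(rnorm(40 * 8), 40, 8)
  m[, 2] <- m[, 1] + rnorm(40, sd = 0.1)
  m[, 3] <- -m[, 1]
  colnames(m) <- sprintf("original_glcm_F%d", 1:8)
  rho <- stats::cor(m, method = "spearman")
  n_clusters <- sapply(c(0.95, 0.75, 0.5, 0.25),
                       function(t) length(unique(cluster_features(rho, t)$cluster)))
  expect_true(all(diff(n_clusters) <= 0))

  cl1 <- cluster_features(rho, 1)
  same <- cl1$cluster[cl1$feature %in% c("original_glcm_F1", "original_glcm_F3")]
  expect_equal(same[1], same[2])        # exact monotone transform, |rho| = 1
  f2 <- cl1$cluster[cl1$feature == "original_glcm_F2"]
  expect_false(f2 == same[1])           # noisy copy is not perfect
})

test_that("the partition is invariant to feature order and all emitted
           clusters pass the audit", {
  withr::local_seed(93)
  sim <- simulate_feature_table(synthetic_preset("redundancy", seed = 93))
  rho <- spearman_matrix(sim$table, "FBP")
  cl <- cluster_features(rho, 0.75)
  # redundant monotone-transform copies co-cluster with their base feature
  base <- cl$cluster[cl$feature == sim$table$features$name[
    grepl("Sim", sim$table$features$name)][1]]
  copies <- cl$cluster[grepl("Redundant", cl$feature)]
  expect_true(all(copies == copies[1]))

  perm <- sample(nrow(rho))
  cl_perm <- cluster_features(rho[perm, perm], 0.75)
  part <- function(x) unname(split(sort(x$feature), x$cluster[order(x$feature)]))
  expect_setequal(part(cl), part(cl_perm))

  # audit re-done here, independently of the in-function assertion
  for (members in split(cl$feature, cl$cluster)) {
    if (length(members) > 1) {
      sub <- abs(rho[members, members])
      expect_gte(min(sub[upper.tri(sub)]), 0.75)
    }
  }
  expect_error(cluster_features(matrix(numeric(0), 0, 0)), "empty")
})
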