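# Independent brute-force oracles used to pin down the analytical
# implementations. These deliberately share no code with the package.

# OCCC as the weighted mean of all pairwise CCCs, each pair weighted by
# Sx^2 + Sy^2 + (mean_x - mean_y)^2 (divisor-n moments).
occc_weighted_oracle <- function(m) {
  J <- ncol(m)
  num <- 0
  den <- 0
  for (j in seq_len(J - 1L)) {
    for (k in seq(j + 1L, J)) {
      x <- m[, j]; y <- m[, k]
      sx <- mean((x - mean(x))^2); sy <- mean((y - mean(y))^2)
      sxy <- mean((x - mean(x)) * (y - mean(y)))
      w <- sx + sy + (mean(x) - mean(y))^2
      num <- num + 2 * sxy
      den <- den + w
    }
  }
  num / den
}

# Exact two-sided Mann-Whitney p by enumerating all C(n, nA) group
# assignments of the pooled sample (no ties assumed).
mw_enum_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  splits <- utils::combn(n, na)
  u_all <- apply(splits, 2L, function(idx) {
    sum(r[idx]) - na * (na + 1) / 2
  })
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# Exact two-sided signed-rank p by enumerating all 2^n sign patterns of the
# nonzero differences (untied absolute values assumed).
sr_enum_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  v_all <- apply(signs, 1L, function(s) sum(r[s]))
  min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
}

# A tiny deterministic complete feature table: n patients x design x the
# given feature column sets.
make_small_table <- function(values_by_feature, n = 6L,
                             design = recon_design(),
                             volumes = NULL) {
  patient_id <- sprintf("p%02d", seq_len(n))
  patients <- tibble::tibble(
    patient_id = patient_id,
    scanner = rep(c("A", "B"), length.out = n),
    tube_voltage = rep(c("100", "120"), each = ceiling(n / 2))[seq_len(n)],
    tumour_volume_cm3 = if (is.null(volumes)) seq(10, 60, length.out = n) else volumes
  )
  vals <- purrr::imap_dfr(values_by_feature, function(m, fname) {
    tibble::tibble(
      patient_id = rep(patient_id, ncol(m)),
      setting = rep(design$settings[seq_len(ncol(m))], each = n),
      feature = fname,
      value = as.vector(m)
    )
  })
  feature_table(vals, patients, design = design)
}
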