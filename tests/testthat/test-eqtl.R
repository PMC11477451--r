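long_counts <- function(m) {
  if (is.null(colnames(m))) colnames(m) <- sprintf("g%03d", seq_len(ncol(m)))
  tibble::as_tibble(m, rownames = "sample_id") |>
    tidyr::pivot_longer(-sample_id, names_to = "feature_id", values_to = "count")
}

test_that("cis filters apply strict MAF/quality thresholds and inclusive window", {
  span <- list(start = 1000000L, end = 1050000L)
  v <- tibble::tibble(
    variant_id = c("v_lowmaf", "v_lowqual", "v_ok", "v_far", "v_edge", "v_maf05"),
    pos = c(1010000L, 1010000L, 1010000L, 1050000L + 500001L,
            1050000L + 500000L, 1010000L),
    maf = c(0.04, 0.2, 0.2, 0.2, 0.2, 0.05),
    imputation_quality = c(0.9, 0.7, 0.9, 0.9, 0.9, 0.9)
  )
  kept <- filter_cis_variants(v, span)
  # the toy of one survivor: low MAF, low quality, out-of-window all excluded
  expect_setequal(kept$variant_id, c("v_ok", "v_edge"))
  expect_true("v_edge" %in% kept$variant_id)      # boundary inclusive
  expect_false("v_maf05" %in% kept$variant_id)    # MAF exactly 0.05 excluded
  expect_equal(nrow(filter_cis_variants(v[2:4, ], span)), 1L)
})

test_that("TMM factors: identical samples give 1, a 2x-scaled sample gives sqrt(2)", {
  set.seed(5)
  a <- rpois(200, 60) + 1L
  ident <- cbind(S1 = a, S2 = a, S3 = a)
  f1 <- tmm_factors(long_counts(t(ident)))
  expect_equal(f1$norm_factor, rep(1, 3))
  # B = 2 x A with equal stated library sizes (mapped totals)
  two <- t(cbind(A = a, B = 2L * a))
  f2 <- tmm_factors(long_counts(two),
                    library_size = c(A = 1e5, B = 1e5))
  f2 <- f2[order(f2$sample_id), ]
  expect_equal(f2$norm_factor, c(1 / sqrt(2), sqrt(2)), tolerance = 1e-8)
  expect_error(tmm_factors(long_counts(rbind(S1 = a * 0L, S2 = a))), "all-zero")
})

test_that("TMM factors are invariant to feature permutation and match the brute-force formula", {
  set.seed(6)
  m <- t(matrix(rnbinom(500 * 5, mu = exp(runif(500, 2, 8)), size = 5),
                ncol = 5, dimnames = list(NULL, paste0("S", 1:5))))
  rs <- colSums(m) > 0
  m <- m[, rs]
  colnames(m) <- paste0("g", seq_len(ncol(m)))
  f <- tmm_factors(long_counts(m))
  perm <- m[, sample(ncol(m))]
  f_perm <- tmm_factors(long_counts(perm))
  expect_equal(f$norm_factor, f_perm$norm_factor)
  oracle <- tmm_oracle(t(m), rowSums(m))
  expect_equal(f$norm_factor, unname(oracle), tolerance = 1e-3)
  # repeat on fresh random matrices
  for (i in 1:10) {
    m2 <- t(matrix(rnbinom(300 * 5, mu = exp(runif(300, 2, 7)), size = 8),
                   ncol = 5, dimnames = list(NULL, paste0("S", 1:5))))
    colnames(m2) <- paste0("g", seq_len(ncol(m2)))
    m2 <- m2[, colSums(m2) > 0]
    f2 <- tmm_factors(long_counts(m2))
    expect_equal(f2$norm_factor, unname(tmm_oracle(t(m2), rowSums(m2))),
                 tolerance = 1e-3)
  }
})

test_that("log-CPM follows the prior-count formula", {
  counts <- tibble::tibble(sample_id = "S1", feature_id = c("a", "b"),
                           count = c(0, 1e6))
  factors <- tibble::tibble(sample_id = "S1", library_size = 1e6, norm_factor = 1)
  lc <- log_cpm(counts, factors)
  expect_equal(lc$log_cpm[1], log2(0.5 / (1e6 + 1) * 1e6), tolerance = 1e-12)
  expect_equal(lc$log_cpm[1], -1, tolerance = 1e-4)
  expect_equal(lc$log_cpm[2], log2((1e6 + 0.5) / (1e6 + 1) * 1e6), tolerance = 1e-12)
  expect_equal(lc$log_cpm[2], log2(1e6), tolerance = 1e-4)
  expect_true(all(is.finite(lc$log_cpm)))
})

test_that("voom weights are near-constant for homoscedastic counts and finite for degenerate input", {
  set.seed(7)
  n <- 40
  m <- matrix(rpois(n * 100, 1000), nrow = n,
              dimnames = list(sprintf("S%02d", 1:n), sprintf("g%03d", 1:100)))
  w <- voom_weights(long_counts(m))
  expect_true(all(w$weight > 0))
  expect_lt(max(w$weight) / min(w$weight), 2)
  # constant counts per feature: zero residual sd must not give infinite weights
  cm <- matrix(rep(c(10, 20, 40, 80, 160, 320, 640, 1280, 2560, 5120, 30, 60),
                   each = n), nrow = n,
               dimnames = list(sprintf("S%02d", 1:n), sprintf("c%02d", 1:12)))
  wc <- voom_weights(long_counts(cm))
  expect_true(all(is.finite(wc$weight) & wc$weight > 0))
  # fewer than 10 features falls back to unit weights
  expect_warning(wu <- voom_weights(long_counts(m[, 1:3])), "unit")
  expect_true(all(wu$weight == 1))
})

test_that("voom weights are invariant to consistent sample reordering", {
  set.seed(8)
  m <- matrix(rpois(30 * 50, exp(runif(50, 3, 7))), nrow = 30, byrow = TRUE)
  m <- t(m)  # samples x features
  dimnames(m) <- list(sprintf("S%02d", 1:50), sprintf("g%02d", 1:30))
  w1 <- voom_weights(long_counts(m))
  w2 <- voom_weights(long_counts(m[sample(nrow(m)), ]))
  key <- function(d) dplyr::arrange(d, sample_id, feature_id)
  expect_equal(key(w1)$weight, key(w2)$weight)
})

test_that("fit_eqtl recovers a planted effect and reduces to OLS with equal weights", {
  set.seed(9)
  n <- 200
  dosage <- rbinom(n, 2, 0.3)
  y <- 0.5 * dosage + rnorm(n, 0, 0.1)
  fit <- fit_eqtl(y, dosage)
  expect_equal(fit$beta, 0.5, tolerance = 0.05)
  ols <- lm(y ~ dosage)
  expect_equal(fit$beta, unname(coef(ols)[2]), tolerance = 1e-10)
  expect_equal(fit$p_value, summary(ols)$coefficients[2, 4], tolerance = 1e-10)
  # equal non-unit weights give the identical estimate
  fitw <- fit_eqtl(y, dosage, weights = rep(2.5, n))
  expect_equal(fitw$beta, fit$beta, tolerance = 1e-12)
  expect_equal(fitw$se, fit$se, tolerance = 1e-10)
  expect_error(fit_eqtl(y, rep(1, n)), "variance")
  # tidy/glance surfaces
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "p.value") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$nobs, n)
})

test_that("fit_eqtl holds its type-I error under the null", {
  set.seed(10)
  n <- 100
  rej <- vapply(1:400, function(i) {
    dosage <- rbinom(n, 2, 0.3)
    y <- rnorm(n)
    fit_eqtl(y, dosage)$p_value < 0.05
  }, logical(1))
  ci <- qbinom(c(0.005, 0.995), 400, 0.05)
  expect_gte(sum(rej), ci[1])
  expect_lte(sum(rej), ci[2])
})

test_that("residual PCs separate a planted batch and are orthonormal", {
  set.seed(11)
  n <- 80
  batch <- rep(c(0, 1), each = n / 2)
  m <- matrix(rnorm(n * 60), n, 60,
              dimnames = list(sprintf("S%02d", 1:n), sprintf("g%02d", 1:60)))
  m <- m + outer(batch, rnorm(60, 0, 2))
  pcs <- residual_pcs(m, k = 3)
  r_pb <- abs(cor(pcs$PC1, batch))
  expect_gt(r_pb, 0.9)
  S <- as.matrix(pcs[, -1])
  expect_equal(crossprod(S), diag(3), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(ncol(residual_pcs(m, k = 0)), 1L)  # sample_id only
  # deterministic sign: recomputation is identical
  expect_equal(pcs, residual_pcs(m, k = 3))
})

test_that("BH adjustment matches the hand example and is monotone", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  set.seed(12)
  p <- runif(50)
  adj <- bh_fdr(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  fam <- rep(c("f1", "f2"), each = 25)
  by_fam <- bh_fdr(p, fam)
  expect_equal(by_fam[fam == "f1"], p.adjust(p[fam == "f1"], "BH"))
})

test_that("gene-level association on summed isoform counts is lncRNA-dominated", {
  for (r in 1:5) {
    cfg <- sim_config(seed = 700 + r, n_samples = 200)
    geno <- sim_haplotypes(cfg, sim_locus(cfg))
    d <- geno$cohort$dosages[, "rs_index"]
    expr <- sim_expression(cfg, d)
    iso <- grep("^SYNPO2L", names(cfg$betas), value = TRUE)
    lc <- log_cpm(expr$counts)
    em <- tidyr::pivot_wider(dplyr::filter(lc, feature_id %in% iso),
                             names_from = feature_id, values_from = log_cpm) |>
      dplyr::arrange(sample_id)
    t_iso <- vapply(iso, function(f) fit_eqtl(em[[f]], d[em$sample_id])$t_stat, 1)
    gene_counts <- expr$counts |>
      dplyr::mutate(feature_id = ifelse(feature_id %in% iso, "SYNPO2L", feature_id)) |>
      dplyr::group_by(sample_id, feature_id) |>
      dplyr::summarise(count = sum(count), .groups = "drop")
    lcg <- log_cpm(gene_counts) |>
      dplyr::filter(feature_id == "SYNPO2L") |>
      tidyr::pivot_wider(names_from = feature_id, values_from = log_cpm) |>
      dplyr::arrange(sample_id)
    t_gene <- fit_eqtl(lcg$SYNPO2L, d[lcg$sample_id])$t_stat
    # summed counts are dominated by the strongly induced lncRNA isoforms:
    # positive effect, at least as strong as the weakest isoform signal
    expect_gt(t_gene, 0)
    expect_gte(abs(t_gene), min(abs(t_iso)))
  }
})

test_that("map_cis_eqtls adjusts within feature families and carries the scan class", {
  set.seed(13)
  n <- 60
  dm <- cbind(v1 = rbinom(n, 2, 0.3), v2 = rbinom(n, 2, 0.4))
  rownames(dm) <- sprintf("S%02d", 1:n)
  em <- cbind(fA = 0.8 * dm[, "v1"] + rnorm(n, 0, 0.5), fB = rnorm(n))
  exprs <- tibble::as_tibble(em, rownames = "sample_id") |>
    tidyr::pivot_longer(-sample_id, names_to = "feature_id", values_to = "log_cpm")
  scan <- map_cis_eqtls(exprs, dm)
  expect_s3_class(scan, "eqtl_scan")
  expect_equal(nrow(scan), 4L)
  fa <- scan[scan$feature_id == "fA", ]
  expect_equal(fa$fdr_bh, p.adjust(fa$p_value, "BH"))
  expect_lt(fa$p_value[fa$variant_id == "v1"], 1e-6)
  expect_s3_class(ggplot2::autoplot(scan), "ggplot")
})
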