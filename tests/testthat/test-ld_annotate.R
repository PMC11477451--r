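test_that("r-squared matches the haplotype-frequency closed form", {
  # complete coupling at p = q = 0.5: D = 0.25, denominator 0.0625
  A <- c(1, 1, 0, 0)
  expect_equal(ld_r2(A, A), 1)
  expect_equal(ld_r2(A, c(1, 1, 0, 0)), 1)
  # enumerated two-SNP haplotype tables vs the D^2 closed form computed here
  set.seed(21)
  for (i in 1:200) {
    n <- 400
    x <- rbinom(n, 1, runif(1, 0.2, 0.8))
    y <- ifelse(rbinom(n, 1, 0.3) == 1, 1 - x, x)
    if (var(x) == 0 || var(y) == 0) next
    pa <- mean(x); pb <- mean(y); pab <- mean(x & y)
    D <- pab - pa * pb
    expect_equal(ld_r2(x, y),
                 D^2 / (pa * (1 - pa) * pb * (1 - pb)), tolerance = 1e-12)
    # identical to the squared Pearson correlation of 0/1 vectors
    expect_equal(ld_r2(x, y), cor(x, y)^2, tolerance = 1e-12)
  }
  expect_error(ld_r2(A, rep(0, 4)), "monomorphic")
})

test_that("independent variants show near-zero r-squared; dosage and haplotype modes agree under HWE", {
  set.seed(22)
  n <- 10000
  x <- rbinom(2 * n, 1, 0.3)
  y <- rbinom(2 * n, 1, 0.4)
  expect_lt(ld_r2(x, y), 0.01)
  # high-LD pair collapsed to dosages
  z <- ifelse(rbinom(2 * n, 1, 0.05) == 1, 1 - x, x)
  r2_hap <- ld_r2(x, z)
  dx <- x[seq(1, 2 * n, 2)] + x[seq(2, 2 * n, 2)]
  dz <- z[seq(1, 2 * n, 2)] + z[seq(2, 2 * n, 2)]
  r2_dos <- ld_r2(dx, dz, mode = "dosage")
  expect_equal(r2_dos, r2_hap, tolerance = 0.02)
})

test_that("proxy discovery uses the min-over-panels rule and includes the index", {
  set.seed(23)
  n <- 400
  idx <- rbinom(n, 1, 0.3)
  tight <- ifelse(rbinom(n, 1, 0.01) == 1, 1 - idx, idx)
  loose <- ifelse(rbinom(n, 1, 0.25) == 1, 1 - idx, idx)
  # v_high is tight in all panels; v_onebad is tight in 4 of 5 panels
  mk_panel <- function(bad) {
    H <- cbind(rs_idx = idx, v_high = tight,
               v_onebad = if (bad) loose else tight)
    list(haplotypes = H)
  }
  panels <- list(P1 = mk_panel(FALSE), P2 = mk_panel(FALSE), P3 = mk_panel(FALSE),
                 P4 = mk_panel(FALSE), P5 = mk_panel(TRUE))
  variants <- tibble::tibble(variant_id = c("rs_idx", "v_high", "v_onebad"),
                             pos = c(1000L, 2000L, 3000L))
  pr <- find_proxies("rs_idx", panels, variants)
  expect_setequal(pr$variant_id, c("rs_idx", "v_high"))
  expect_equal(pr$r2_min_panels[pr$variant_id == "rs_idx"], 1)
  # invariant to panel ordering
  pr_rev <- find_proxies("rs_idx", rev(panels), variants)
  expect_equal(dplyr::arrange(pr, variant_id)$r2_min_panels,
               dplyr::arrange(pr_rev, variant_id)$r2_min_panels)
  expect_error(find_proxies("rs_idx", list(P1 = list(haplotypes = cbind(rs_idx = rep(0L, n)))),
                            variants), "monomorphic")
})

test_that("the synthetic LD block yields exactly the planted proxies plus the index", {
  cfg <- sim_config(seed = 24, n_samples = 50)
  locus <- sim_locus(cfg)
  geno <- sim_haplotypes(cfg, locus)
  panels <- lapply(geno$panels, function(p) list(haplotypes = p$haplotypes))
  pr <- find_proxies("rs_index", panels, geno$variants)
  expect_setequal(pr$variant_id, c("rs_index", geno$truth$proxy_ids))
})

test_that("positional classification reproduces known classes and amino-acid changes", {
  cfg <- sim_config(seed = 25, n_samples = 10)
  locus <- sim_locus(cfg)
  geno <- sim_haplotypes(cfg, locus)
  cls <- classify_positional(geno$variants, locus$models, locus$cds_regions,
                             locus$cds_seqs)
  get <- function(id, col) cls[[col]][cls$variant_id == id]
  expect_equal(get("rs_reg", "positional_class"), "intergenic")
  expect_equal(get("rs_mis_g2s", "positional_class"), "missense")
  expect_equal(get("rs_mis_g2s", "amino_acid_change"), "G2S")
  expect_equal(get("rs_mis_p707l", "amino_acid_change"), "P707L")
  expect_equal(get("rs_mis_s833y", "amino_acid_change"), "S833Y")
  expect_equal(get("rs_syn1", "positional_class"), "synonymous")
  expect_equal(get("rs_utr1", "positional_class"), "utr3")
  expect_equal(get("rs_index", "positional_class"), "intronic")
  # reference mismatch is caught
  bad <- geno$variants[geno$variants$variant_id == "rs_mis_g2s", ]
  bad$ref <- setdiff(c("A", "C", "G", "T"), c(bad$ref, bad$alt))[1]
  expect_error(classify_positional(bad, locus$models, locus$cds_regions,
                                   locus$cds_seqs), "mismatch")
})

test_that("classification agrees with a per-base brute-force annotator", {
  cfg <- sim_config(seed = 26, n_samples = 10)
  locus <- sim_locus(cfg)
  set.seed(26)
  pos1 <- sample(9000:32500, 300)
  ref <- locus$genome[pos1]
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
  snps <- tibble::tibble(variant_id = sprintf("s%03d", seq_along(pos1)),
                         chrom = "chr10", pos = pos1, ref = ref, alt = alt)
  cls <- classify_positional(snps, locus$models, locus$cds_regions, locus$cds_seqs)
  oracle <- vapply(seq_along(pos1), function(i) {
    classify_oracle(pos1[i], ref[i], alt[i], locus$models, locus$cds_regions,
                    locus$cds_seqs)
  }, "")
  expect_equal(cls$positional_class, oracle)
})

test_that("regulatory prioritization reproduces a hand-computed ranking and is stable", {
  snps <- tibble::tibble(
    variant_id = sprintf("v%d", 1:6),
    pos = c(100L, 200L, 300L, 400L, 500L, 600L),
    dnase1_hs = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE),
    h3k4me1 = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    h3k4me3 = FALSE,
    h3k9ac = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    positional_class = c("intergenic", "intronic", "intronic", "intergenic",
                         "intergenic", "intronic")
  )
  ranked <- prioritize_regulatory(snps)
  # hand scores: v1 = 1+1+1 = 3, v2 = 0+1+0 = 1, v3 = 1, v4 = 0+1+1 = 2,
  #              v5 = 0+0+1 = 1, v6 = 0
  expect_equal(ranked$variant_id, c("v1", "v4", "v2", "v3", "v5", "v6"))
  expect_equal(ranked$score, c(3L, 2L, 1L, 1L, 1L, 0L))
  # no evidence anywhere: positional order preserved (stable sort)
  none <- dplyr::mutate(snps, dnase1_hs = FALSE, h3k4me1 = FALSE,
                        h3k9ac = FALSE, positional_class = "intronic")
  expect_equal(prioritize_regulatory(none)$variant_id, none$variant_id)
  ev <- count_evidence(snps)
  expect_equal(ev$n_dnase1_hs, 2L)
  expect_equal(ev$n_enhancer_promoter, 3L)
})

test_that("marks join plus prioritization puts the planted regulatory SNP first", {
  cfg <- sim_config(seed = 27, n_samples = 20)
  study <- simulate_study(cfg)
  cls <- classify_positional(study$genotypes$variants, study$locus$models,
                             study$locus$cds_regions, study$locus$cds_seqs)
  ann <- dplyr::left_join(cls, study$marks, by = "variant_id")
  proxies <- ann[ann$variant_id %in% c(study$truth$proxy_ids, "rs_index"), ]
  ranked <- prioritize_regulatory(proxies, gene_spans(study$locus$models))
  expect_equal(ranked$variant_id[1], "rs_reg")
  expect_equal(ranked$candidate_rank[ranked$variant_id == "rs_reg"], 1L)
})
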