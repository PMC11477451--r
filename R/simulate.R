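#' Simulation configuration
#'
#' Defines the synthetic study conditions: a two-gene locus (one
#' single-isoform gene on the minus strand; one four-isoform gene with three
#' transcription start sites, one alternative splice donor, two lncRNA
#' isoforms whose first exons are 200/280-nt prefixes of each other, and a
#' shared last exon), an LD block of proxies around an index SNP across five
#' population panels, allele-dependent isoform abundances with
#' opposite-sign effects on the two genes, and uniform-coverage Poisson read
#' sampling.
#'
#' @param seed Master integer seed; every random draw derives from it.
#' @param n_samples Analysis-cohort size (number of diploid individuals).
#' @param index_maf Minor allele frequency of the index SNP, in (0, 0.5].
#' @param n_proxies Number of high-LD proxies of the index SNP.
#' @param proxy_r2_target Target r-squared of proxies with the index.
#' @param n_decoys Number of independent (low-LD) decoy variants.
#' @param n_panels,panel_n Number of reference panels and diploid
#'   individuals per panel.
#' @param betas Named per-feature log2 effect of alt-allele dosage; defaults
#'   follow the opposite-direction pattern: negative for the single-isoform
#'   gene and the full-length coding isoform, positive for the short coding
#'   isoform and both lncRNAs.
#' @param coverage_mean Mean sequencing depth (reads covering a base) over
#'   the locus at baseline expression.
#' @param read_length Single-end fragment length in nt.
#' @param sigma Multiplicative log2-normal noise SD on per-sample densities.
#' @param latent_gamma Loading of the shared latent factor that drives the
#'   inverse coexpression of the two genes (and of two planted background
#'   gene blocks).
#' @param n_background Number of background genes (used for normalization,
#'   voom weights, coexpression and gene sets).
#' @param flag_fraction Fraction of non-planted proxies receiving one random
#'   chromatin flag.
#' @param lnc_exon_lengths Lengths (nt) of the two lncRNA first exons
#'   (prefix relationship; the two lncRNAs share their start coordinate).
#' @param include_age Include age as a covariate column.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_samples = 200L, index_maf = 0.3,
                       n_proxies = 10L, proxy_r2_target = 0.95,
                       n_decoys = 10L, n_panels = 5L, panel_n = 100L,
                       betas = c(MYOZ1 = -0.5, SYNPO2L.2 = -0.3,
                                 SYNPO2L.1 = 0.3, SYNPO2L.N1 = 0.5,
                                 SYNPO2L.N2 = 0.5),
                       coverage_mean = 100, read_length = 100L,
                       sigma = 0.2, latent_gamma = 0.15,
                       n_background = 200L, flag_fraction = 0.3,
                       lnc_exon_lengths = c(200L, 280L),
                       include_age = TRUE) {
  stopifnot(n_samples > 0, n_proxies >= 0, n_decoys >= 0, n_panels > 0,
            panel_n > 0, coverage_mean >= 0, n_background >= 0,
            index_maf > 0, index_maf <= 0.5,
            proxy_r2_target > 0, proxy_r2_target <= 1,
            length(lnc_exon_lengths) == 2L, lnc_exon_lengths[2] > lnc_exon_lengths[1])
  structure(list(
    seed = as.integer(seed), n_samples = as.integer(n_samples),
    index_maf = index_maf, n_proxies = as.integer(n_proxies),
    proxy_r2_target = proxy_r2_target, n_decoys = as.integer(n_decoys),
    n_panels = as.integer(n_panels), panel_n = as.integer(panel_n),
    betas = betas, coverage_mean = coverage_mean,
    read_length = as.integer(read_length), sigma = sigma,
    latent_gamma = latent_gamma, n_background = as.integer(n_background),
    flag_fraction = flag_fraction,
    lnc_exon_lengths = as.integer(lnc_exon_lengths),
    include_age = isTRUE(include_age)
  ), class = "sim_config")
}

sim_chrom <- "chr10"

locus_geometry <- function(config) {
  l1 <- config$lnc_exon_lengths[1]
  l2 <- config$lnc_exon_lengths[2]
  tibble(
    gene_id = c("MYOZ1", "MYOZ1",
                rep("SYNPO2L", 4L + 2L + 2L + 2L)),
    transcript_id = c("MYOZ1.1", "MYOZ1.1",
                      rep("SYNPO2L.2", 4), rep("SYNPO2L.1", 2),
                      rep("SYNPO2L.N1", 2), rep("SYNPO2L.N2", 2)),
    biotype = c(rep("protein_coding", 2 + 4 + 2), rep("lncRNA", 4)),
    chrom = sim_chrom,
    start = c(10000L, 12000L,
              20000L, 22000L, 24000L, 30000L,
              26000L, 30000L,
              28000L, 30000L,
              28000L, 30000L),
    end = c(10600L, 12400L,
            20900L, 22800L, 24700L, 31500L,
            26750L, 31500L,
            28000L + l1, 31500L,
            28000L + l2, 31500L),
    strand = c("-", "-", rep("+", 10))
  ) |>
    group_by(.data$transcript_id) |>
    mutate(exon_rank = if (first(.data$strand) == "-") rev(seq_len(n())) else seq_len(n())) |>
    ungroup()
}

cds_geometry <- function() {
  tibble(
    isoform_id = c("SYNPO2L.2", "SYNPO2L.2", "SYNPO2L.2", "SYNPO2L.2",
                   "SYNPO2L.1", "SYNPO2L.1",
                   "MYOZ1.1", "MYOZ1.1"),
    chrom = sim_chrom,
    start = c(20060L, 22000L, 24000L, 30000L, 26090L, 30000L, 12010L, 10300L),
    end = c(20900L, 22800L, 24700L, 30660L, 26750L, 30660L, 12400L, 10600L),
    strand = c(rep("+", 6), "-", "-")
  )
}

# genomic 0-based position of a 1-based CDS coordinate (plus strand only)
cds_to_genomic <- function(cds_regions, isoform_id, cds_pos) {
  reg <- cds_regions[cds_regions$isoform_id == isoform_id, ]
  reg <- reg[order(reg$start), ]
  off <- cds_pos - 1L
  for (j in seq_len(nrow(reg))) {
    len <- reg$end[j] - reg$start[j]
    if (off < len) return(reg$start[j] + off)
    off <- off - len
  }
  abort("CDS position beyond CDS length")
}

#' Generate the synthetic gene locus
#'
#' Builds the two-gene locus geometry, a deterministic random genome
#' sequence with planted codons (so that specific proxies are missense or
#' synonymous when classified), CDS intervals and CDS sequences.
#'
#' @param config A [sim_config()].
#' @return A list: `models` (exon tibble), `cds_regions`, `cds_seqs` (named,
#'   transcript orientation), `genome` (character vector of bases, 0-based
#'   indexing via position + 1).
#' @export
sim_locus <- function(config) {
  models <- locus_geometry(config)
  cds_regions <- cds_geometry()
  set.seed(derive_seed(config$seed, 11L))
  genome <- sample(c("A", "C", "G", "T"), 32000L, replace = TRUE)
  # planted codons in SYNPO2L.2 (1-based CDS coordinates)
  plant <- function(iso, codon, bases) {
    for (k in 0:2) {
      g0 <- cds_to_genomic(cds_regions, iso, (codon - 1L) * 3L + 1L + k)
      genome[g0 + 1L] <<- substr(bases, k + 1L, k + 1L)
    }
  }
  plant("SYNPO2L.2", 2L, "GGC")    # G2S target codon (glycine)
  plant("SYNPO2L.2", 707L, "CCA")  # P707L target codon (proline)
  plant("SYNPO2L.2", 833L, "TCT")  # S833Y target codon (serine)
  plant("SYNPO2L.2", 900L, "CTG")  # synonymous target codon (leucine)
  cds_seqs <- purrr::map_chr(split(cds_regions, cds_regions$isoform_id), function(reg) {
    reg <- reg[order(reg$start), ]
    s <- paste(unlist(lapply(seq_len(nrow(reg)), function(j) {
      genome[(reg$start[j] + 1L):reg$end[j]]
    })), collapse = "")
    if (reg$strand[1] == "-") {
      s <- chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
    }
    s
  })
  list(models = models, cds_regions = cds_regions, cds_seqs = cds_seqs,
       genome = genome)
}

sim_variant_table <- function(config, locus) {
  cds <- locus$cds_regions
  g2s_pos0 <- cds_to_genomic(cds, "SYNPO2L.2", 4L)      # codon 2, first base
  p707_pos0 <- cds_to_genomic(cds, "SYNPO2L.2", 2120L)  # codon 707, middle base
  s833_pos0 <- cds_to_genomic(cds, "SYNPO2L.2", 2498L)  # codon 833, middle base
  syn_pos0 <- cds_to_genomic(cds, "SYNPO2L.2", 2700L)   # codon 900, third base
  special <- tibble(
    variant_id = c("rs_reg", "rs_mis_g2s", "rs_mis_p707l", "rs_mis_s833y",
                   "rs_syn1", "rs_utr1", "rs_int1", "rs_int2"),
    pos0 = c(16000L, g2s_pos0, p707_pos0, s833_pos0, syn_pos0,
             31000L, 27500L, 29000L),
    alt = c("T", "A", "T", "A", "A", "C", "G", "T")
  )
  n_extra <- max(0L, config$n_proxies - nrow(special))
  if (n_extra > 0L) {
    special <- bind_rows(special, tibble(
      variant_id = sprintf("rs_proxy%02d", seq_len(n_extra)),
      pos0 = as.integer(14000L + 400L * seq_len(n_extra)),
      alt = "A"
    ))
  }
  proxies <- special[seq_len(min(config$n_proxies, nrow(special))), ]
  if (!"rs_reg" %in% proxies$variant_id && config$n_proxies >= 1L) {
    proxies$variant_id[1] <- "rs_reg"; proxies$pos0[1] <- 16000L; proxies$alt[1] <- "T"
  }
  decoys <- tibble(
    variant_id = sprintf("rs_decoy%02d", seq_len(config$n_decoys)),
    pos0 = as.integer(33000L + 1500L * seq_len(config$n_decoys)),
    alt = "G"
  )
  if (config$n_decoys >= 2L) decoys$pos0[config$n_decoys - 1L] <- 300000L
  if (config$n_decoys >= 1L) decoys$pos0[config$n_decoys] <- 600000L
  vt <- bind_rows(
    tibble(variant_id = "rs_index", pos0 = 25500L, alt = "C", role = "index"),
    proxies |> mutate(role = "proxy"),
    decoys |> mutate(role = "decoy")
  )
  ref <- purrr::map_chr(seq_len(nrow(vt)), function(i) {
    p <- vt$pos0[i]
    if (p + 1L <= length(locus$genome)) locus$genome[p + 1L] else "A"
  })
  vt$ref <- ref
  vt$alt <- ifelse(vt$alt == vt$ref, chartr("ACGT", "CGTA", vt$ref), vt$alt)
  vt |>
    mutate(chrom = sim_chrom, pos = .data$pos0 + 1L) |>
    arrange(.data$pos) |>
    select("variant_id", "chrom", "pos", "ref", "alt", "role")
}

gen_haplotypes <- function(n_hap, variants, config) {
  flip_p <- (1 - sqrt(config$proxy_r2_target)) / 2
  idx <- stats::rbinom(n_hap, 1L, config$index_maf)
  # guard: index must be polymorphic
  if (sum(idx) == 0L) idx[1L] <- 1L
  if (sum(idx) == n_hap) idx[1L] <- 0L
  H <- matrix(0L, n_hap, nrow(variants),
              dimnames = list(NULL, variants$variant_id))
  decoy_freq <- 0.15 + 0.25 * (seq_len(sum(variants$role == "decoy")) %%
                                 5L) / 5
  d <- 0L
  for (j in seq_len(nrow(variants))) {
    H[, j] <- switch(variants$role[j],
      index = idx,
      proxy = {
        flips <- stats::rbinom(n_hap, 1L, flip_p)
        as.integer(xor(idx, flips))
      },
      decoy = {
        d <- d + 1L
        stats::rbinom(n_hap, 1L, decoy_freq[d])
      })
  }
  H
}

#' Generate haplotype panels, cohort genotypes and variant metadata
#'
#' The index SNP is drawn at the configured MAF; proxies are obtained by
#' copying the index haplotype and flipping alleles with probability
#' `f = (1 - sqrt(r2_target)) / 2`, giving expected r-squared of about
#' `(1 - 2f)^2`; decoys are drawn independently. The analysis cohort and
#' each of the reference panels are generated independently with the same
#' scheme.
#'
#' @param config A [sim_config()].
#' @param locus Output of [sim_locus()] (for reference alleles).
#' @return A list: `variants` (tibble with `maf` from cohort dosages and
#'   `imputation_quality`), `cohort` (list with `haplotypes`, `dosages`
#'   samples x variants, `sample_ids`), `panels` (named list of haplotype
#'   panels), `truth` (proxy ids, planted regulatory SNP id).
#' @export
sim_haplotypes <- function(config, locus) {
  variants <- sim_variant_table(config, locus)
  set.seed(derive_seed(config$seed, 23L))
  cohort_h <- gen_haplotypes(2L * config$n_samples, variants, config)
  dos <- cohort_h[seq(1, nrow(cohort_h), by = 2), , drop = FALSE] +
    cohort_h[seq(2, nrow(cohort_h), by = 2), , drop = FALSE]
  sample_ids <- sprintf("S%03d", seq_len(config$n_samples))
  rownames(dos) <- sample_ids
  panel_names <- c("CEU", "TSI", "FIN", "GBR", "IBS",
                   sprintf("P%02d", seq_len(max(0, config$n_panels - 5L))))
  panel_names <- panel_names[seq_len(config$n_panels)]
  panels <- lapply(seq_len(config$n_panels), function(k) {
    set.seed(derive_seed(config$seed, 100L + k))
    list(panel_id = panel_names[k],
         haplotypes = gen_haplotypes(2L * config$panel_n, variants, config))
  })
  names(panels) <- panel_names
  set.seed(derive_seed(config$seed, 31L))
  qual <- 0.85 + 0.14 * stats::runif(nrow(variants))
  low_q <- which(variants$role == "decoy")
  if (length(low_q) >= 2L) qual[low_q[2L]] <- 0.55  # exercises the quality filter
  alt_freq <- colMeans(dos) / 2
  variants <- variants |>
    mutate(maf = unname(pmin(alt_freq, 1 - alt_freq)[.data$variant_id]),
           imputation_quality = round(qual, 3))
  list(variants = variants,
       cohort = list(haplotypes = cohort_h, dosages = dos,
                     sample_ids = sample_ids),
       panels = panels,
       truth = list(proxy_ids = variants$variant_id[variants$role == "proxy"],
                    index_id = "rs_index",
                    planted_regulatory = "rs_reg"))
}

locus_feature_info <- function(config) {
  l1 <- config$lnc_exon_lengths[1]
  l2 <- config$lnc_exon_lengths[2]
  tibble(
    feature_id = c("MYOZ1", "SYNPO2L.2", "SYNPO2L.1", "SYNPO2L.N1", "SYNPO2L.N2"),
    signature_length = c(1000L, 700L, 750L, l1, l2),
    rel_expression = c(1, 0.5, 0.7, 1.5, 0.8),
    latent_loading = c(-1, 1, 1, 1, 1)
  )
}

#' Simulate allele-dependent expression counts
#'
#' Per sample, the read density of feature i is
#' `base_i * 2^(beta_i * dosage + gamma_i * L + eps)` with `L` a standard
#' normal latent factor shared across features (opposite loadings on the two
#' genes) and `eps ~ N(0, sigma^2)` log2-normal noise. Counts are Poisson
#' draws of density times signature length. Background genes carry no
#' genotype effect; two 20-gene blocks load positively / negatively on the
#' latent factor (the substrate for coexpression and gene-set enrichment).
#'
#' @param config A [sim_config()].
#' @param dosage Dosage vector of the causal (index) SNP, one per sample.
#' @param seed_offset Offset added to the derived seed (vary across
#'   replicates).
#' @param betas Optional override of the per-feature effects (e.g. all zero
#'   for null simulations).
#' @return A list: `counts` (long tibble `sample_id`, `feature_id`,
#'   `count`), `densities` (samples x locus features matrix of true
#'   densities in reads/base), `covariates` (tibble `sample_id`, `sex`, and
#'   optionally `age`), `latent`, `betas`, `feature_info`.
#' @export
sim_expression <- function(config, dosage, seed_offset = 0L, betas = NULL) {
  betas <- betas %||% config$betas
  info <- locus_feature_info(config)
  stopifnot(all(info$feature_id %in% names(betas)))
  n <- length(dosage)
  sample_ids <- sprintf("S%03d", seq_len(n))
  set.seed(derive_seed(config$seed, 41L + seed_offset))
  L <- stats::rnorm(n)
  sex <- stats::rbinom(n, 1L, 0.5)
  age <- round(stats::rnorm(n, 65, 8), 1)
  base <- config$coverage_mean / config$read_length * info$rel_expression
  dens <- sapply(seq_len(nrow(info)), function(i) {
    eps <- stats::rnorm(n, 0, config$sigma)
    base[i] * 2^(betas[[info$feature_id[i]]] * dosage +
                   config$latent_gamma * info$latent_loading[i] * L + eps)
  })
  colnames(dens) <- info$feature_id
  rownames(dens) <- sample_ids
  locus_counts <- sapply(seq_len(nrow(info)), function(i) {
    stats::rpois(n, dens[, i] * info$signature_length[i])
  })
  colnames(locus_counts) <- info$feature_id
  bg <- NULL
  if (config$n_background > 0L) {
    g_ids <- sprintf("BG%03d", seq_len(config$n_background))
    lam <- exp(stats::rnorm(config$n_background, log(500), 0.8))
    gam <- numeric(config$n_background)
    k <- min(20L, config$n_background)
    gam[seq_len(k)] <- config$latent_gamma
    if (config$n_background >= 40L) gam[21:40] <- -config$latent_gamma
    bg <- sapply(seq_len(config$n_background), function(g) {
      eps <- stats::rnorm(n, 0, config$sigma)
      stats::rpois(n, lam[g] * 2^(gam[g] * L + eps))
    })
    colnames(bg) <- g_ids
  }
  cm <- cbind(locus_counts, bg)
  rownames(cm) <- sample_ids
  counts <- as_tibble(cm, rownames = "sample_id") |>
    pivot_longer(-"sample_id", names_to = "feature_id", values_to = "count")
  cov <- tibble(sample_id = sample_ids, sex = sex)
  if (config$include_age) cov$age <- age
  list(counts = counts, densities = dens, covariates = cov, latent = L,
       betas = betas, feature_info = info)
}

#' Simulate uniform-coverage reads over the locus
#'
#' For each sample and isoform, fragments are placed uniformly within the
#' isoform's exons with Poisson totals of density times length. Fragments
#' are truncated at disjoint signature-region boundaries so that the
#' expected count of each region is exactly density times region length (the
#' uniform-coverage counting model is unbiased); boundary-spanning reads in
#' real data are handled by the counting modes of [count_reads()].
#'
#' @param config A [sim_config()].
#' @param densities Samples x isoforms density matrix (reads/base), as from
#'   [sim_expression()] (`MYOZ1` column is taken as isoform `MYOZ1.1`).
#' @param locus Output of [sim_locus()].
#' @param seed_offset Offset added to the derived seed.
#' @return Read tibble `chrom`, `start`, `end`, `sample_id`, ordered by
#'   sample then position.
#' @export
sim_reads <- function(config, densities, locus, seed_offset = 0L) {
  models <- locus$models
  colnames(densities)[colnames(densities) == "MYOZ1"] <- "MYOZ1.1"
  sig <- select_signature_regions(models)
  regions <- build_disjoint_regions(sig)
  bnds <- sort(unique(c(regions$start, regions$end)))
  set.seed(derive_seed(config$seed, 57L + seed_offset))
  out <- vector("list", nrow(densities) * n_distinct(models$transcript_id))
  k <- 0L
  for (s in seq_len(nrow(densities))) {
    sid <- rownames(densities)[s]
    for (iso in unique(models$transcript_id)) {
      d <- densities[s, iso]
      ex <- models |> filter(.data$transcript_id == iso)
      units <- purrr::map(seq_len(nrow(ex)), function(j) {
        cuts <- c(ex$start[j], bnds[bnds > ex$start[j] & bnds < ex$end[j]], ex$end[j])
        tibble(start = cuts[-length(cuts)], end = cuts[-1])
      }) |> list_rbind()
      n_r <- stats::rpois(nrow(units), d * (units$end - units$start))
      tot <- sum(n_r)
      if (tot == 0L) next
      starts <- unlist(purrr::map(seq_len(nrow(units)), function(j) {
        if (n_r[j] == 0L) return(integer())
        units$start[j] + sample.int(units$end[j] - units$start[j], n_r[j],
                                    replace = TRUE) - 1L
      }))
      ends <- pmin(starts + config$read_length,
                   rep(units$end, n_r))
      k <- k + 1L
      out[[k]] <- tibble(chrom = sim_chrom, start = starts, end = ends,
                         sample_id = sid)
    }
  }
  list_rbind(out[seq_len(k)]) |>
    arrange(.data$sample_id, .data$start, .data$end)
}

#' Simulate chromatin-mark annotations
#'
#' The planted regulatory SNP (intergenic between the two genes) receives
#' DNase1 hypersensitivity plus H3K4me1 and H3K9ac; a configurable fraction
#' of the other proxies receive one random flag; decoys receive none.
#'
#' @param config A [sim_config()].
#' @param variants Variant tibble from [sim_haplotypes()] (with `role`).
#' @return Chromatin annotation tibble (`variant_id`, four logical flags,
#'   `tissue`).
#' @export
sim_marks <- function(config, variants) {
  set.seed(derive_seed(config$seed, 71L))
  flags <- c("dnase1_hs", "h3k4me1", "h3k4me3", "h3k9ac")
  out <- variants |>
    select("variant_id") |>
    mutate(dnase1_hs = FALSE, h3k4me1 = FALSE, h3k4me3 = FALSE,
           h3k9ac = FALSE, tissue = "fetal heart")
  planted <- variants$variant_id == "rs_reg"
  out$dnase1_hs[planted] <- TRUE
  out$h3k4me1[planted] <- TRUE
  out$h3k9ac[planted] <- TRUE
  others <- which(variants$role == "proxy" & !planted)
  if (length(others) > 0L && config$flag_fraction > 0) {
    flagged <- others[stats::runif(length(others)) < config$flag_fraction]
    for (i in flagged) {
      out[[sample(flags, 1L)]][i] <- TRUE
    }
  }
  out
}

sim_gene_sets <- function(config) {
  if (config$n_background < 40L) return(list())
  g_ids <- sprintf("BG%03d", seq_len(config$n_background))
  sets <- list(SET_LATENT_POS = g_ids[1:20], SET_LATENT_NEG = g_ids[21:40])
  set.seed(derive_seed(config$seed, 83L))
  rest <- g_ids[-(1:40)]
  for (k in seq_len(8L)) {
    sets[[sprintf("SET_RANDOM_%02d", k)]] <- sort(sample(rest, min(15L, length(rest))))
  }
  sets
}

write_vcf <- function(path, variants, haplotypes, imputation_quality = NULL,
                      sample_prefix = "S") {
  n_hap <- nrow(haplotypes)
  n <- n_hap / 2L
  sids <- sprintf("%s%03d", sample_prefix, seq_len(n))
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", sim_chrom),
    '##INFO=<ID=R2,Number=1,Type=Float,Description="Imputation quality">',
    '##INFO=<ID=AF,Number=A,Type=Float,Description="Alt allele frequency">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Phased genotype">',
    '##FORMAT=<ID=DS,Number=1,Type=Float,Description="Alt allele dosage">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sids), collapse = "\t")
  )
  qual <- imputation_quality %||% variants$imputation_quality %||%
    rep(NA_real_, nrow(variants))
  body <- purrr::map_chr(seq_len(nrow(variants)), function(j) {
    h1 <- haplotypes[seq(1, n_hap, 2), variants$variant_id[j]]
    h2 <- haplotypes[seq(2, n_hap, 2), variants$variant_id[j]]
    gt <- sprintf("%d|%d:%d", h1, h2, h1 + h2)
    af <- mean(c(h1, h2))
    paste(c(variants$chrom[j], variants$pos[j], variants$variant_id[j],
            variants$ref[j], variants$alt[j], ".", "PASS",
            sprintf("R2=%s;AF=%s", fmt_num(qual[j], 4), fmt_num(af, 4)),
            "GT:DS", gt), collapse = "\t")
  })
  write_lines_lf(c(hdr, body), path)
}

write_marks_tsv <- function(marks, path) {
  lines <- c(paste(c("variant_id", "dnase1_hs", "h3k4me1", "h3k4me3",
                     "h3k9ac", "tissue"), collapse = "\t"),
             sprintf("%s\t%d\t%d\t%d\t%d\t%s", marks$variant_id,
                     marks$dnase1_hs, marks$h3k4me1, marks$h3k4me3,
                     marks$h3k9ac, marks$tissue))
  write_lines_lf(lines, path)
}

write_gmt <- function(sets, path) {
  lines <- purrr::imap_chr(sets, function(g, nm) {
    paste(c(nm, "synthetic", g), collapse = "\t")
  })
  write_lines_lf(unname(lines), path)
}

write_reads_bed <- function(reads, path) {
  write_lines_lf(sprintf("%s\t%d\t%d\t%s", reads$chrom, reads$start,
                         reads$end, reads$sample_id), path)
}

#' Run the full synthetic study
#'
#' Generates the locus, panels and cohort genotypes, allele-dependent
#' expression, reads, chromatin marks and toy gene sets, and (optionally)
#' writes every artifact as plain text: `locus.gtf`, `cohort.vcf`, one
#' `panel_<ID>.vcf` per reference panel, `reads.bed`, `marks.tsv`,
#' `sets.gmt`, `cds.fa`, `cds_regions.tsv`, `counts.tsv`, `covariates.tsv`
#' and `truth.json`. Identical configurations (including the seed) produce
#' byte-identical files.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed); `NULL` skips file
#'   output.
#' @param write_reads Write the read BED (can be large at high coverage).
#' @return A list with all generated components and `truth` ground-truth
#'   values, invisibly when `dir` is given.
#' @export
simulate_study <- function(config = sim_config(), dir = NULL,
                           write_reads = TRUE) {
  locus <- sim_locus(config)
  geno <- sim_haplotypes(config, locus)
  dosage <- geno$cohort$dosages[, "rs_index"]
  expr <- sim_expression(config, dosage)
  reads <- sim_reads(config, expr$densities, locus)
  marks <- sim_marks(config, geno$variants)
  sets <- sim_gene_sets(config)
  truth <- list(
    betas = as.list(expr$betas),
    proxy_ids = geno$truth$proxy_ids,
    index_id = geno$truth$index_id,
    planted_regulatory = geno$truth$planted_regulatory,
    base_density = stats::setNames(
      config$coverage_mean / config$read_length * expr$feature_info$rel_expression,
      expr$feature_info$feature_id),
    densities = expr$densities
  )
  res <- list(config = config, locus = locus, genotypes = geno, expr = expr,
              reads = reads, marks = marks, sets = sets, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_gene_models_gtf(locus$models, file.path(dir, "locus.gtf"))
    write_vcf(file.path(dir, "cohort.vcf"), geno$variants,
              geno$cohort$haplotypes)
    for (pn in names(geno$panels)) {
      write_vcf(file.path(dir, sprintf("panel_%s.vcf", pn)), geno$variants,
                geno$panels[[pn]]$haplotypes, sample_prefix = substr(pn, 1, 1))
    }
    if (write_reads) write_reads_bed(reads, file.path(dir, "reads.bed"))
    write_marks_tsv(marks, file.path(dir, "marks.tsv"))
    write_gmt(sets, file.path(dir, "sets.gmt"))
    write_lines_lf(unlist(purrr::imap(locus$cds_seqs, function(s, nm) {
      c(paste0(">", nm), s)
    })), file.path(dir, "cds.fa"))
    write_lines_lf(c("isoform_id\tchrom\tstart\tend\tstrand",
                     sprintf("%s\t%s\t%d\t%d\t%s", locus$cds_regions$isoform_id,
                             locus$cds_regions$chrom, locus$cds_regions$start,
                             locus$cds_regions$end, locus$cds_regions$strand)),
                   file.path(dir, "cds_regions.tsv"))
    cm <- counts_to_matrix(expr$counts)
    write_lines_lf(c(paste(c("sample_id", colnames(cm)), collapse = "\t"),
                     vapply(seq_len(nrow(cm)), function(i) {
                       paste(c(rownames(cm)[i], cm[i, ]), collapse = "\t")
                     }, character(1))),
                   file.path(dir, "counts.tsv"))
    cov_lines <- c(paste(names(expr$covariates), collapse = "\t"),
                   do.call(sprintf, c(
                     list(paste(rep("%s", ncol(expr$covariates)), collapse = "\t")),
                     lapply(expr$covariates, as.character))))
    write_lines_lf(cov_lines, file.path(dir, "covariates.tsv"))
    jsonlite::write_json(
      list(betas = truth$betas, proxy_ids = truth$proxy_ids,
           index_id = truth$index_id,
           planted_regulatory = truth$planted_regulatory,
           base_density = as.list(truth$base_density)),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = 10, pretty = TRUE)
    return(invisible(res))
  }
  res
}
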