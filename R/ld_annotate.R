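#' Pairwise linkage disequilibrium r-squared
#'
#' Haplotype mode (0/1 vectors, one entry per haplotype) computes
#' `r^2 = D^2 / (pA qA pB qB)` from haplotype frequencies, with
#' `D = pAB - pA pB`. Dosage mode (values in `[0, 2]`) computes the squared
#' Pearson correlation of dosages; under Hardy-Weinberg equilibrium the two
#' agree.
#'
#' @param x,y Numeric vectors of equal length: haplotype alleles in `{0, 1}`
#'   or genotype dosages in `[0, 2]`.
#' @param mode `"auto"` infers haplotype mode when all values are 0/1.
#' @return r-squared in `[0, 1]`; errors if either variant is monomorphic.
#' @export
ld_r2 <- function(x, y, mode = c("auto", "haplotype", "dosage")) {
  mode <- match.arg(mode)
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (mode == "auto") {
    mode <- if (all(x %in% c(0, 1)) && all(y %in% c(0, 1))) "haplotype" else "dosage"
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    abort("r-squared undefined: a variant is monomorphic in this panel")
  }
  if (mode == "haplotype") {
    pa <- mean(x); pb <- mean(y)
    pab <- mean(x == 1 & y == 1)
    D <- pab - pa * pb
    D^2 / (pa * (1 - pa) * pb * (1 - pb))
  } else {
    stats::cor(x, y)^2
  }
}

#' Find LD proxies of an index variant across panels
#'
#' Keeps variants within a window of the index whose r-squared with the
#' index exceeds the threshold in EVERY panel (min over panels), the
#' strictest reading of "high LD in all groups". The index itself is always
#' included.
#'
#' @param index_id Variant id of the index SNP; must be polymorphic in every
#'   panel.
#' @param panels Named list of panels; each panel is a list with
#'   `haplotypes` (haplotypes x variants 0/1 matrix) or `dosages`
#'   (samples x variants), with variant ids as column names.
#' @param variants Variant tibble with `variant_id` and `pos`.
#' @param r2_min LD threshold.
#' @param window_bp Window around the index position (inclusive).
#' @param strict Use `r2 > r2_min` (`TRUE`, default) or `r2 >= r2_min`.
#' @return Tibble `variant_id`, `pos`, one `r2_<panel>` column per panel,
#'   `r2_min_panels`, filtered to the proxy set and sorted by position.
#' @export
find_proxies <- function(index_id, panels, variants, r2_min = 0.8,
                         window_bp = 200000, strict = TRUE) {
  assert_cols(variants, c("variant_id", "pos"), "variant table")
  if (is.null(names(panels))) names(panels) <- paste0("panel", seq_along(panels))
  geno_of <- function(panel) panel$haplotypes %||% panel$dosages
  for (pn in names(panels)) {
    g <- geno_of(panels[[pn]])
    if (!index_id %in% colnames(g)) {
      abort(sprintf("index %s absent from panel %s", index_id, pn))
    }
    if (stats::var(g[, index_id]) == 0) {
      abort(sprintf("index %s is monomorphic in panel %s", index_id, pn))
    }
  }
  idx_pos <- variants$pos[variants$variant_id == index_id]
  if (length(idx_pos) != 1L) abort("index variant not found in variant table")
  cand <- variants |>
    filter(abs(.data$pos - idx_pos) <= window_bp)
  r2_cols <- map(names(panels), function(pn) {
    g <- geno_of(panels[[pn]])
    map_dbl(cand$variant_id, function(v) {
      if (v == index_id) return(1)
      if (!v %in% colnames(g)) return(NA_real_)
      if (stats::var(g[, v]) == 0) return(0)
      ld_r2(g[, index_id], g[, v])
    })
  })
  names(r2_cols) <- paste0("r2_", names(panels))
  res <- bind_cols(cand |> select("variant_id", "pos"), as_tibble(r2_cols)) |>
    mutate(r2_min_panels = do.call(pmin, c(across(starts_with("r2_")), na.rm = FALSE)))
  keep <- if (strict) res$r2_min_panels > r2_min else res$r2_min_panels >= r2_min
  keep[is.na(keep)] <- FALSE
  res |>
    filter(keep | .data$variant_id == index_id) |>
    arrange(.data$pos)
}

#' Read a chromatin-annotation table
#'
#' Tab-separated with columns `variant_id`, `dnase1_hs`, `h3k4me1`,
#' `h3k4me3`, `h3k9ac` (0/1) and optionally `tissue`.
#'
#' @param path TSV path.
#' @return Tibble with logical flag columns.
#' @export
read_marks <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  assert_cols(df, c("variant_id", "dnase1_hs", "h3k4me1", "h3k4me3", "h3k9ac"),
              "chromatin annotation table")
  df |>
    mutate(across(c("dnase1_hs", "h3k4me1", "h3k4me3", "h3k9ac"), as.logical))
}

#' Classify SNVs positionally against gene models
#'
#' Assigns each single-nucleotide variant one class with priority
#' CDS > 3' UTR > intronic > intergenic when it overlaps several features.
#' Within the CDS, the reference and alternate codons are translated
#' (strand-aware) with the standard genetic code: `missense` when the amino
#' acid changes, `synonymous` otherwise, reported with the amino-acid change
#' (e.g. `G2S`). `utr3` covers exonic positions 3' of the CDS of a coding
#' isoform; other gene-body positions (introns, non-coding exons) are
#' `intronic`; positions outside all gene spans are `intergenic`.
#'
#' @param snps Tibble with `variant_id`, `chrom`, `pos` (1-based), `ref`,
#'   `alt` (single bases).
#' @param models Gene-model exon tibble.
#' @param cds_regions Tibble of CDS intervals: `isoform_id`, `chrom`,
#'   `start`, `end` (0-based half-open), `strand`; summed lengths per
#'   isoform must be multiples of 3.
#' @param cds_seqs Named character vector (or `Biostrings::DNAStringSet`) of
#'   CDS sequences (5'->3' in transcript orientation) per coding isoform.
#' @return `snps` with `positional_class` and `amino_acid_change` columns.
#' @export
classify_positional <- function(snps, models, cds_regions, cds_seqs) {
  assert_cols(snps, c("variant_id", "chrom", "pos", "ref", "alt"), "SNP table")
  if (!is.character(cds_seqs)) cds_seqs <- as.character(cds_seqs)
  cds_len <- cds_regions |>
    group_by(.data$isoform_id) |>
    summarise(len = sum(.data$end - .data$start), .groups = "drop")
  if (any(cds_len$len %% 3L != 0L)) {
    abort(sprintf("CDS length not a multiple of 3 for isoform %s",
                  cds_len$isoform_id[cds_len$len %% 3L != 0L][1]))
  }
  spans <- gene_spans(models)
  out <- snps |>
    mutate(cls = purrr::pmap(list(.data$variant_id, .data$chrom, .data$pos,
                                  .data$ref, .data$alt),
                             classify_one, models = models, spans = spans,
                             cds_regions = cds_regions, cds_seqs = cds_seqs))
  out |>
    mutate(positional_class = map_chr(.data$cls, "class"),
           amino_acid_change = map_chr(.data$cls, "aa_change")) |>
    select(-"cls")
}

classify_one <- function(variant_id, chrom, pos, ref, alt,
                         models, spans, cds_regions, cds_seqs) {
  pos0 <- pos - 1L  # 0-based position of the variant base
  in_span <- spans |>
    filter(.data$chrom == !!chrom, pos0 >= .data$start, pos0 < .data$end)
  if (nrow(in_span) == 0L) {
    return(list(class = "intergenic", aa_change = NA_character_))
  }
  # CDS first
  hit_cds <- cds_regions |>
    filter(.data$chrom == !!chrom, pos0 >= .data$start, pos0 < .data$end)
  if (nrow(hit_cds) > 0L) {
    iso <- hit_cds$isoform_id[1]
    reg <- cds_regions |>
      filter(.data$isoform_id == iso) |>
      arrange(.data$start)
    strand <- reg$strand[1]
    seq <- toupper(cds_seqs[[iso]])
    # transcript-orientation offset of pos0 within the spliced CDS
    if (strand == "+") {
      prior <- sum(pmax(0, pmin(reg$end, pos0) - reg$start))
    } else {
      prior <- sum(pmax(0, reg$end - pmax(reg$start, pos0 + 1L)))
    }
    cds_pos <- prior + 1L  # 1-based within CDS
    ref_t <- if (strand == "+") ref else chartr("ACGT", "TGCA", ref)
    alt_t <- if (strand == "+") alt else chartr("ACGT", "TGCA", alt)
    if (substr(seq, cds_pos, cds_pos) != ref_t) {
      abort(sprintf("reference mismatch for %s: CDS %s has %s at CDS position %d, VCF ref is %s",
                    variant_id, iso, substr(seq, cds_pos, cds_pos), cds_pos, ref))
    }
    codon_i <- (cds_pos - 1L) %/% 3L
    within <- (cds_pos - 1L) %% 3L + 1L
    codon_ref <- substr(seq, codon_i * 3L + 1L, codon_i * 3L + 3L)
    codon_alt <- codon_ref
    substr(codon_alt, within, within) <- alt_t
    gc <- Biostrings::GENETIC_CODE
    aa_ref <- unname(gc[codon_ref])
    aa_alt <- unname(gc[codon_alt])
    change <- sprintf("%s%d%s", aa_ref, codon_i + 1L, aa_alt)
    if (aa_ref == aa_alt) {
      return(list(class = "synonymous", aa_change = change))
    }
    return(list(class = "missense", aa_change = change))
  }
  # 3' UTR: exonic within a coding isoform, 3' of its CDS
  coding_iso <- unique(cds_regions$isoform_id)
  exon_hits <- models |>
    filter(.data$chrom == !!chrom, pos0 >= .data$start, pos0 < .data$end,
           .data$transcript_id %in% coding_iso)
  if (nrow(exon_hits) > 0L) {
    for (iso in unique(exon_hits$transcript_id)) {
      reg <- cds_regions |> filter(.data$isoform_id == iso)
      strand <- reg$strand[1]
      downstream <- if (strand == "+") pos0 >= max(reg$end) else pos0 < min(reg$start)
      if (downstream) return(list(class = "utr3", aa_change = NA_character_))
    }
  }
  list(class = "intronic", aa_change = NA_character_)
}

#' Rank candidate regulatory variants by chromatin evidence
#'
#' Score = 1 point for DNase1 hypersensitivity, 1 point for any
#' enhancer/promoter histone mark (H3K4me1, H3K4me3 or H3K9ac), and 1 bonus
#' point for an intergenic position between the two target gene spans (the
#' profile of a between-gene enhancer variant). Sorting is stable: score
#' descending, then genomic position.
#'
#' @param snps Tibble with `variant_id`, `pos`, flag columns (`dnase1_hs`,
#'   `h3k4me1`, `h3k4me3`, `h3k9ac`) and `positional_class`.
#' @param gene_span_pair Optional two-row tibble from [gene_spans()]; when
#'   given, the intergenic bonus applies only between the two spans.
#' @return The input with `enhancer_promoter`, `intergenic_between`,
#'   `score` and `candidate_rank` columns, ranked best first.
#' @export
prioritize_regulatory <- function(snps, gene_span_pair = NULL) {
  assert_cols(snps, c("variant_id", "pos", "dnase1_hs", "h3k4me1",
                      "h3k4me3", "h3k9ac"), "annotated SNP table")
  between <- if (!is.null(gene_span_pair) && nrow(gene_span_pair) == 2L) {
    gap_lo <- min(gene_span_pair$end)
    gap_hi <- max(gene_span_pair$start)
    (snps$pos - 1L) >= gap_lo & (snps$pos - 1L) < gap_hi
  } else rep(TRUE, nrow(snps))
  cls <- if ("positional_class" %in% names(snps)) snps$positional_class else "intergenic"
  out <- snps |>
    mutate(
      enhancer_promoter = .data$h3k4me1 | .data$h3k4me3 | .data$h3k9ac,
      intergenic_between = cls == "intergenic" & between,
      score = as.integer(.data$dnase1_hs) + as.integer(.data$enhancer_promoter) +
        as.integer(.data$intergenic_between)
    )
  ord <- order(-out$score, out$pos)
  out <- out[ord, ]
  out$candidate_rank <- seq_len(nrow(out))
  out
}

#' Count SNPs per chromatin-evidence class
#'
#' @param snps Annotated SNP tibble with chromatin flags.
#' @return One-row tibble: totals of SNPs, DNase1-hypersensitive SNPs and
#'   SNPs within enhancer/promoter marks.
#' @export
count_evidence <- function(snps) {
  tibble(
    n_snps = nrow(snps),
    n_dnase1_hs = sum(snps$dnase1_hs),
    n_enhancer_promoter = sum(snps$h3k4me1 | snps$h3k4me3 | snps$h3k9ac)
  )
}
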