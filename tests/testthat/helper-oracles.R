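# Independent brute-force oracles used to cross-check the package's own
# implementations. These are deliberately written as naive enumerations.

# per-base membership of a set of intervals (0-based half-open)
brute_membership <- function(intervals) {
  if (nrow(intervals) == 0L) return(list())
  lo <- min(intervals$start); hi <- max(intervals$end)
  bases <- lo:(hi - 1L)
  memb <- lapply(bases, function(b) {
    sort(unique(intervals$isoform_id[intervals$start <= b & b < intervals$end]))
  })
  names(memb) <- as.character(bases)
  memb[lengths(memb) > 0L]
}

# membership per base implied by a disjoint-region table
regions_membership <- function(regions) {
  out <- list()
  for (j in seq_len(nrow(regions))) {
    for (b in regions$start[j]:(regions$end[j] - 1L)) {
      out[[as.character(b)]] <- sort(regions$members[[j]])
    }
  }
  out
}

# weighted trimmed mean of M-values, coded from the published recipe
tmm_oracle <- function(counts, lib) {
  # counts: features x samples
  uq <- apply(counts, 2, stats::quantile, probs = 0.75) / lib
  ref <- which.min(abs(uq - mean(uq)))
  f <- sapply(seq_len(ncol(counts)), function(j) {
    y <- counts[, j]; r <- counts[, ref]
    ok <- y > 0 & r > 0
    y <- y[ok]; r <- r[ok]
    M <- log2((y / lib[j]) / (r / lib[ref]))
    A <- 0.5 * log2((y / lib[j]) * (r / lib[ref]))
    if (max(abs(M)) < 1e-6) return(1)
    v <- (lib[j] - y) / (lib[j] * y) + (lib[ref] - r) / (lib[ref] * r)
    n <- length(M)
    loM <- floor(n * 0.3) + 1; hiM <- n + 1 - loM
    loA <- floor(n * 0.05) + 1; hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    2^(sum(M[keep] / v[keep]) / sum(1 / v[keep]))
  })
  f / exp(mean(log(f)))
}

# step-by-step running-sum enrichment score, independent of the package code;
# |deviation| ties (within 1e-9) go to the earlier rank position
gsea_es_oracle <- function(scores, set, p = 1) {
  ord <- order(scores, decreasing = TRUE)
  g <- names(scores)[ord]
  s <- scores[ord]
  hit <- g %in% set
  nr <- sum(abs(s[hit])^p)
  running <- numeric(length(g))
  level <- 0
  for (i in seq_along(g)) {
    if (hit[i]) {
      level <- level + (if (nr == 0) 1 / sum(hit) else abs(s[i])^p / nr)
    } else {
      level <- level - 1 / (length(g) - sum(hit))
    }
    running[i] <- level
  }
  unname(running[which(abs(running) > max(abs(running)) - 1e-9)[1]])
}

# naive positional annotator: checks each feature type base by base
classify_oracle <- function(pos1, ref, alt, models, cds_regions, cds_seqs) {
  b <- pos1 - 1L
  spans <- lapply(split(models, models$gene_id), function(g) {
    c(min(g$start), max(g$end))
  })
  inside_gene <- any(vapply(spans, function(sp) b >= sp[1] && b < sp[2], logical(1)))
  if (!inside_gene) return("intergenic")
  for (iso in unique(cds_regions$isoform_id)) {
    reg <- cds_regions[cds_regions$isoform_id == iso, ]
    reg <- reg[order(reg$start), ]
    cds_bases <- unlist(lapply(seq_len(nrow(reg)), function(j) reg$start[j]:(reg$end[j] - 1L)))
    if (b %in% cds_bases) {
      if (reg$strand[1] == "+") {
        i <- match(b, cds_bases)
        seq <- toupper(cds_seqs[[iso]])
        rt <- ref; at <- alt
      } else {
        i <- match(b, rev(cds_bases))
        seq <- toupper(cds_seqs[[iso]])
        rt <- chartr("ACGT", "TGCA", ref); at <- chartr("ACGT", "TGCA", alt)
      }
      codon_i <- (i - 1L) %/% 3L
      within <- (i - 1L) %% 3L + 1L
      cr <- substr(seq, codon_i * 3 + 1, codon_i * 3 + 3)
      ca <- cr
      substr(ca, within, within) <- at
      gc <- Biostrings::GENETIC_CODE
      return(if (gc[cr] == gc[ca]) "synonymous" else "missense")
    }
  }
  for (iso in unique(cds_regions$isoform_id)) {
    ex <- models[models$transcript_id == iso, ]
    exonic <- any(ex$start <= b & b < ex$end)
    if (!exonic) next
    reg <- cds_regions[cds_regions$isoform_id == iso, ]
    if (reg$strand[1] == "+" && b >= max(reg$end)) return("utr3")
    if (reg$strand[1] == "-" && b < min(reg$start)) return("utr3")
  }
  "intronic"
}

# random non-overlapping-per-isoform interval sets on one chromosome
random_signature_set <- function(n_iso = 4, max_pos = 2000) {
  iso <- sprintf("I%d", seq_len(n_iso))
  rows <- lapply(iso, function(id) {
    k <- sample(1:3, 1)
    starts <- sort(sample(0:(max_pos - 60), k))
    lens <- sample(10:50, k, replace = TRUE)
    tibble::tibble(isoform_id = id, chrom = "chrT",
                   start = starts, end = pmin(starts + lens, max_pos))
  })
  out <- dplyr::bind_rows(rows)
  out[out$end > out$start, ]
}
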