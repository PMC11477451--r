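#' Read gene models from GTF or BED12
#'
#' Parses transcript models into a tidy exon table. GTF input follows the
#' Ensembl dialect (`gene_id`/`transcript_id` attributes, 1-based closed
#' coordinates); BED12 input carries one transcript per line with block
#' structure. Internally all coordinates are 0-based half-open, so
#' `end - start` is the exon length.
#'
#' @param path Path to a GTF or BED12 file.
#' @param format `"auto"` (by file extension), `"gtf"` or `"bed12"`.
#' @return A tibble with one row per exon and columns `gene_id`,
#'   `transcript_id`, `biotype`, `chrom`, `start`, `end`, `strand`,
#'   `exon_rank` (1 = most 5' exon). Exons are sorted by genomic start within
#'   each transcript.
#' @export
read_gene_models <- function(path, format = c("auto", "gtf", "bed12")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed1?2?$", path, ignore.case = TRUE)) "bed12" else "gtf"
  }
  if (length(readLines(path, n = 1L, warn = FALSE)) == 0L) {
    warn(sprintf("gene model file '%s' is empty; returning no models", path))
    return(empty_gene_models())
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = if (format == "bed12") "bed" else "gtf"),
    error = function(e) abort(sprintf("failed to parse '%s': %s", path, conditionMessage(e)))
  )
  if (format == "gtf") {
    gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
    if (length(gr) == 0L) {
      warn(sprintf("no exon records in '%s'", path))
      return(empty_gene_models())
    }
    bt <- S4Vectors::mcols(gr)$gene_biotype
    if (is.null(bt)) bt <- S4Vectors::mcols(gr)$transcript_biotype
    if (is.null(bt)) bt <- NA_character_
    models <- tibble(
      gene_id = as.character(S4Vectors::mcols(gr)$gene_id),
      transcript_id = as.character(S4Vectors::mcols(gr)$transcript_id),
      biotype = as.character(bt),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      # GRanges is 1-based closed; convert to 0-based half-open
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr))
    )
  } else {
    if (is.null(S4Vectors::mcols(gr)$blocks)) {
      abort(sprintf("'%s' lacks BED12 block columns", path))
    }
    exl <- rtracklayer::blocks(gr)  # exons in genomic coordinates, 1-based
    models <- map(seq_along(gr), function(i) {
      b <- exl[[i]]
      tibble(
        gene_id = as.character(S4Vectors::mcols(gr)$name[i]),
        transcript_id = as.character(S4Vectors::mcols(gr)$name[i]),
        biotype = NA_character_,
        chrom = as.character(GenomicRanges::seqnames(gr)[i]),
        start = GenomicRanges::start(b) - 1L,
        end = GenomicRanges::end(b),
        strand = as.character(GenomicRanges::strand(gr)[i])
      )
    }) |> list_rbind()
  }
  models <- models |>
    arrange(.data$transcript_id, .data$start) |>
    group_by(.data$transcript_id) |>
    mutate(exon_rank = if (first(.data$strand) == "-") rev(seq_len(n())) else seq_len(n())) |>
    ungroup()
  validate_gene_models(models)
  models
}

empty_gene_models <- function() {
  tibble(gene_id = character(), transcript_id = character(),
         biotype = character(), chrom = character(),
         start = integer(), end = integer(), strand = character(),
         exon_rank = integer())
}

#' Validate a gene-model exon table
#'
#' Checks the structural invariants of an exon table: positive-length exons,
#' a single chromosome and strand per transcript, and no overlapping exons
#' within one transcript.
#'
#' @param models Exon tibble as returned by [read_gene_models()].
#' @return The input, invisibly; errors describe the first violation found.
#' @export
validate_gene_models <- function(models) {
  assert_cols(models, c("gene_id", "transcript_id", "chrom", "start", "end", "strand"),
              "gene model table")
  if (nrow(models) == 0L) return(invisible(models))
  bad <- models |> filter(.data$end <= .data$start)
  if (nrow(bad) > 0L) {
    abort(sprintf("exon with end <= start in transcript %s", bad$transcript_id[1]))
  }
  per_tx <- models |>
    group_by(.data$transcript_id) |>
    summarise(
      n_chrom = n_distinct(.data$chrom),
      n_strand = n_distinct(.data$strand),
      overlap = any(utils::head(sort(.data$end), -1) > utils::tail(sort(.data$start), -1)),
      .groups = "drop"
    )
  if (any(per_tx$n_chrom > 1L) || any(per_tx$n_strand > 1L)) {
    abort(sprintf("transcript %s spans multiple chromosomes or strands",
                  per_tx$transcript_id[per_tx$n_chrom > 1L | per_tx$n_strand > 1L][1]))
  }
  if (any(per_tx$overlap)) {
    abort(sprintf("transcript %s has overlapping exons",
                  per_tx$transcript_id[per_tx$overlap][1]))
  }
  invisible(models)
}

#' Write gene models as GTF
#'
#' Emits Ensembl-dialect exon records (1-based closed coordinates), restoring
#' the on-disk convention from the internal 0-based half-open one.
#'
#' @param models Exon tibble as returned by [read_gene_models()].
#' @param path Output path.
#' @param source Value for the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gene_models_gtf <- function(models, path, source = "isoqtl") {
  validate_gene_models(models)
  models <- models |> arrange(.data$gene_id, .data$transcript_id, .data$start)
  bt <- models$biotype %||% rep(NA_character_, nrow(models))
  attr_str <- sprintf('gene_id "%s"; transcript_id "%s";%s',
                      models$gene_id, models$transcript_id,
                      ifelse(is.na(bt), "", sprintf(' gene_biotype "%s";', bt)))
  lines <- sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s",
                   models$chrom, source, models$start + 1L, models$end,
                   models$strand, attr_str)
  write_lines_lf(lines, path)
}

#' Summarise gene spans
#'
#' @param models Exon tibble.
#' @return One row per gene: `gene_id`, `chrom`, `strand`, `start`, `end`
#'   (0-based half-open span covering every exon of every isoform) and
#'   `n_isoforms`.
#' @export
gene_spans <- function(models) {
  validate_gene_models(models)
  models |>
    group_by(.data$gene_id) |>
    summarise(
      chrom = first(.data$chrom),
      strand = first(.data$strand),
      start = min(.data$start),
      end = max(.data$end),
      n_isoforms = n_distinct(.data$transcript_id),
      .groups = "drop"
    )
}

#' Select isoform signature regions
#'
#' For each isoform of each gene, selects the most 3' exon (strand-aware:
#' largest end on `+`, smallest start on `-`) that is not shared by all
#' isoforms of the gene, preferring exons unique to exactly one isoform.
#' Sharing is decided by exon-level identity (same start and end); partially
#' overlapping signatures (e.g. a 200-nt first exon that is a prefix of a
#' 280-nt one) are both returned and resolved downstream by the disjoint
#' partition and deconvolution. A single-isoform gene contributes its whole
#' exon set.
#'
#' @param models Exon tibble.
#' @return Tibble of signature intervals: `gene_id`, `isoform_id`, `chrom`,
#'   `start`, `end`, `strand`.
#' @export
select_signature_regions <- function(models) {
  validate_gene_models(models)
  if (nrow(models) == 0L) abort("no isoforms in gene model table")
  models |>
    group_by(.data$gene_id) |>
    group_split() |>
    map(signature_for_gene) |>
    list_rbind()
}

signature_for_gene <- function(gene_models) {
  n_iso <- n_distinct(gene_models$transcript_id)
  out_cols <- function(df) {
    df |>
      transmute(gene_id = .data$gene_id, isoform_id = .data$transcript_id,
                chrom = .data$chrom, start = .data$start, end = .data$end,
                strand = .data$strand)
  }
  if (n_iso == 1L) {
    return(out_cols(gene_models))
  }
  # exon-identity sharing: how many isoforms carry this exact exon
  shared <- gene_models |>
    group_by(.data$chrom, .data$start, .data$end) |>
    mutate(n_carriers = n_distinct(.data$transcript_id)) |>
    ungroup()
  tx_ids <- unique(gene_models$transcript_id)
  picks <- map(tx_ids, function(id) {
      tx <- shared |> filter(.data$transcript_id == id)
      cand <- tx |> filter(.data$n_carriers < n_iso)
      if (nrow(cand) == 0L) return(NULL)
      uniq <- cand |> filter(.data$n_carriers == 1L)
      if (nrow(uniq) > 0L) cand <- uniq
      # most 3' first, ties broken toward the longer region
      if (first(cand$strand) == "-") {
        cand <- cand |> arrange(.data$start, .data$start - .data$end)
      } else {
        cand <- cand |> arrange(desc(.data$end), .data$start - .data$end)
      }
      cand[1L, ]
    })
  missing_ids <- tx_ids[purrr::map_lgl(picks, is.null)]
  if (length(missing_ids) > 0L) {
    partner <- if (length(missing_ids) > 1L) missing_ids[2L] else setdiff(tx_ids, missing_ids)[1L]
    abort(sprintf(
      "isoform(s) %s have no distinguishing exonic region (indistinguishable pair %s / %s)",
      paste(missing_ids, collapse = ", "), missing_ids[1L], partner))
  }
  picks |> list_rbind() |> out_cols()
}

#' Partition signature intervals into disjoint regions
#'
#' Partitions the union of all signature intervals at every interval boundary
#' into maximal segments of constant isoform membership. The segments tile
#' the union exactly: no gaps inside input intervals and no overlaps between
#' segments.
#'
#' @param signatures Tibble with columns `isoform_id`, `chrom`, `start`,
#'   `end` (0-based half-open) as from [select_signature_regions()].
#' @return Tibble of regions: `region_id`, `chrom`, `start`, `end`, `length`,
#'   `members` (list-column of isoform ids) and `n_members`, sorted by
#'   position.
#' @export
build_disjoint_regions <- function(signatures) {
  if (nrow(signatures) == 0L) {
    return(tibble(region_id = character(), chrom = character(),
                  start = integer(), end = integer(), length = integer(),
                  members = list(), n_members = integer()))
  }
  assert_cols(signatures, c("isoform_id", "chrom", "start", "end"), "signature table")
  gr <- GenomicRanges::GRanges(
    seqnames = signatures$chrom,
    ranges = IRanges::IRanges(start = signatures$start + 1L, end = signatures$end)
  )
  dj <- GenomicRanges::disjoin(gr)
  hits <- GenomicRanges::findOverlaps(dj, gr)
  members <- split(signatures$isoform_id[S4Vectors::subjectHits(hits)],
                   factor(S4Vectors::queryHits(hits), levels = seq_along(dj)))
  members <- lapply(members, function(m) sort(unique(m)))
  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(dj)),
    start = GenomicRanges::start(dj) - 1L,
    end = GenomicRanges::end(dj),
    members = unname(members)
  ) |>
    mutate(n_members = purrr::map_int(.data$members, base::length),
           length = .data$end - .data$start) |>
    arrange(.data$chrom, .data$start) |>
    mutate(region_id = sprintf("region_%03d", row_number())) |>
    select("region_id", "chrom", "start", "end", "length", "members", "n_members")
  out
}

#' Write disjoint regions as BED6
#'
#' The BED name field is the comma-joined member isoform ids; the score field
#' is the member count.
#'
#' @param regions Tibble from [build_disjoint_regions()].
#' @param path Output path.
#' @param strand Strand character recycled across regions (BED column 6).
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path, strand = "+") {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   regions$chrom, regions$start, regions$end,
                   purrr::map_chr(regions$members, paste, collapse = ","),
                   regions$n_members, strand)
  write_lines_lf(lines, path)
}
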