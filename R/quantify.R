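#' Read aligned-read intervals from BED
#'
#' One interval per read; the BED name field carries the sample id. This is
#' the plain-text stand-in for BAM alignments used throughout the package.
#'
#' @param path BED file (>= 4 columns).
#' @return Tibble with `chrom`, `start`, `end` (0-based half-open),
#'   `sample_id`.
#' @export
read_reads_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "sample_id",
                                        "score", "strand")[1:4],
                          colClasses = c("character", "integer", "integer", "character"),
                          fill = TRUE)
  as_tibble(df)
}

#' Count reads over disjoint regions
#'
#' A read increments a region if it overlaps it by at least one base. Reads
#' spanning a boundary between regions are, in the default `"fractional"`
#' mode, split evenly across the regions they touch (1/k each); `"any"`
#' counts the read fully into every region it touches; `"strict"` counts a
#' read only when it overlaps exactly one region (boundary-spanning reads
#' are dropped). Reads that overlap
#' no region (or lie on chromosomes absent from the region table) contribute
#' to the per-sample library size only.
#'
#' @param reads Tibble of read intervals (`chrom`, `start`, `end`,
#'   `sample_id`), as from [read_reads_bed()] or [sim_reads()].
#' @param regions Disjoint-region tibble from [build_disjoint_regions()].
#' @param overlap_mode Counting mode for boundary-spanning reads.
#' @param library_size Optional named vector of total mapped reads per
#'   sample; defaults to the number of read intervals per sample.
#' @return Tibble with one row per sample x region: `sample_id`,
#'   `region_id`, `count`, `library_size`. Every region appears for every
#'   sample (zero-filled).
#' @export
count_reads <- function(reads, regions,
                        overlap_mode = c("fractional", "any", "strict"),
                        library_size = NULL) {
  overlap_mode <- match.arg(overlap_mode)
  assert_cols(reads, c("chrom", "start", "end", "sample_id"), "read table")
  stopifnot(all(reads$end > reads$start))
  samples <- sort(unique(reads$sample_id))
  if (is.null(library_size)) {
    library_size <- table(factor(reads$sample_id, levels = samples))
    library_size <- stats::setNames(as.numeric(library_size), samples)
  }
  grid <- tidyr::expand_grid(sample_id = samples, region_id = regions$region_id)
  if (nrow(reads) == 0L || nrow(regions) == 0L) {
    out <- grid |> mutate(count = 0, library_size = 0)
    return(out)
  }
  r_gr <- GenomicRanges::GRanges(reads$chrom,
                                 IRanges::IRanges(reads$start + 1L, reads$end))
  g_gr <- GenomicRanges::GRanges(regions$chrom,
                                 IRanges::IRanges(regions$start + 1L, regions$end))
  hits <- GenomicRanges::findOverlaps(r_gr, g_gr)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  n_off <- nrow(reads) - length(unique(qh))
  if (n_off > 0L) {
    message(sprintf("%d read(s) overlap no region; counted into library size only", n_off))
  }
  if (length(qh) == 0L) {
    return(grid |>
             mutate(count = 0,
                    library_size = unname(library_size[.data$sample_id])))
  }
  k <- tabulate(qh, nbins = nrow(reads))  # regions touched per read
  w <- switch(overlap_mode,
              fractional = 1 / k[qh],
              any = rep(1, length(qh)),
              strict = as.numeric(k[qh] == 1L))
  counted <- tibble(sample_id = reads$sample_id[qh],
                    region_id = regions$region_id[sh],
                    w = w) |>
    group_by(.data$sample_id, .data$region_id) |>
    summarise(count = sum(.data$w), .groups = "drop")
  grid |>
    left_join(counted, by = c("sample_id", "region_id")) |>
    mutate(count = tidyr::replace_na(.data$count, 0),
           library_size = unname(library_size[.data$sample_id]))
}

# regions x isoforms incidence of lengths: A[j, i] = length_j if isoform i
# is a member of region j, else 0
incidence_matrix <- function(regions) {
  isoforms <- sort(unique(unlist(regions$members)))
  A <- matrix(0, nrow = nrow(regions), ncol = length(isoforms),
              dimnames = list(regions$region_id, isoforms))
  for (j in seq_len(nrow(regions))) {
    A[j, regions$members[[j]]] <- regions$length[j]
  }
  A
}

#' Deconvolve region counts into per-isoform abundances
#'
#' Under a uniform per-base coverage model, the expected count of a disjoint
#' region is `length_j * sum(density_i)` over its member isoforms. Per
#' sample, per-isoform read densities are recovered by non-negative least
#' squares on the region-length incidence matrix, and the deconvolved count
#' of an isoform is its density times its signature length (the summed
#' length of the regions it belongs to). For exactly determined systems this
#' conserves reads: summed deconvolved counts equal summed region counts
#' within each connected block of overlapping regions.
#'
#' @param counts Tibble from [count_reads()].
#' @param regions Disjoint-region tibble with `members` list-column.
#' @param tol Negativity tolerance: an unconstrained solution more negative
#'   than `-tol` triggers a warning before clamping.
#' @return Tibble with one row per sample x isoform: `sample_id`,
#'   `isoform_id`, `density` (reads per base), `signature_length`,
#'   `deconvolved_count`, `library_size`.
#' @export
deconvolve <- function(counts, regions, tol = 1e-8) {
  assert_cols(counts, c("sample_id", "region_id", "count"), "count table")
  A <- incidence_matrix(regions)
  if (ncol(A) == 0L) abort("no isoform members in region table")
  if (qr(A)$rank < ncol(A)) {
    # name confounded isoforms: identical membership columns
    key <- apply(A > 0, 2, paste, collapse = "")
    dup <- names(key)[key %in% key[duplicated(key)]]
    abort(sprintf("incidence matrix is rank deficient; confounded isoforms: %s",
                  paste(dup, collapse = ", ")))
  }
  sig_len <- colSums((A > 0) * regions$length)
  wide <- counts |>
    select("sample_id", "region_id", "count") |>
    pivot_wider(names_from = "region_id", values_from = "count") |>
    arrange(.data$sample_id)
  b_mat <- as.matrix(wide[, rownames(A), drop = FALSE])
  lib <- counts |> distinct(.data$sample_id, .data$library_size)
  res <- map(seq_len(nrow(wide)), function(s) {
    b <- as.numeric(b_mat[s, ])
    if (all(b == 0)) {
      dens <- rep(0, ncol(A))
    } else {
      unc <- qr.coef(qr(A), b)
      unc[is.na(unc)] <- 0
      if (any(unc < -tol)) {
        warn(sprintf("sample %s: unconstrained density %.3g < 0; clamping via NNLS",
                     wide$sample_id[s], min(unc)))
      }
      dens <- pracma::lsqnonneg(A, b)$x
    }
    tibble(sample_id = wide$sample_id[s],
           isoform_id = colnames(A),
           density = dens,
           signature_length = unname(sig_len),
           deconvolved_count = dens * unname(sig_len))
  }) |> list_rbind()
  if ("library_size" %in% names(counts)) {
    res <- res |> left_join(lib, by = "sample_id")
  }
  res
}

#' Convert deconvolved counts to RPKM
#'
#' RPKM = deconvolved count / (signature length in kb) / (library size in
#' millions of mapped reads).
#'
#' @param abundance Tibble from [deconvolve()]; must carry `library_size`.
#' @return The input with an `rpkm` column added.
#' @export
to_rpkm <- function(abundance) {
  assert_cols(abundance,
              c("deconvolved_count", "signature_length", "library_size"),
              "abundance table")
  bad <- abundance |> filter(.data$library_size <= 0)
  if (nrow(bad) > 0L) {
    abort(sprintf("library size is zero for sample(s): %s",
                  paste(unique(bad$sample_id), collapse = ", ")))
  }
  abundance |>
    mutate(rpkm = .data$deconvolved_count /
             (.data$signature_length / 1000) / (.data$library_size / 1e6))
}
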