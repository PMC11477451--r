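#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_segment geom_rect
#'   geom_line geom_hline geom_boxplot geom_jitter labs theme_minimal
#'   facet_wrap
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Plot a gene locus model
#'
#' Exon boxes per isoform with a line through each transcript span.
#'
#' @param models Exon tibble from [read_gene_models()].
#' @return A ggplot object.
#' @export
plot_locus <- function(models) {
  tx <- models |>
    group_by(.data$gene_id, .data$transcript_id) |>
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop") |>
    arrange(.data$start) |>
    mutate(y = row_number())
  ex <- models |> left_join(tx |> select("transcript_id", "y"), by = "transcript_id")
  ggplot() +
    geom_segment(data = tx, aes(x = .data$start, xend = .data$end,
                                y = .data$y, yend = .data$y),
                 linewidth = 0.3, colour = "grey50") +
    geom_rect(data = ex, aes(xmin = .data$start, xmax = .data$end,
                             ymin = .data$y - 0.3, ymax = .data$y + 0.3,
                             fill = .data$gene_id)) +
    ggplot2::scale_y_continuous(breaks = tx$y, labels = tx$transcript_id) +
    labs(x = "genomic position (bp)", y = NULL, fill = "gene") +
    theme_minimal()
}

#' Expression stratified by genotype dosage
#'
#' @param exprs Long expression tibble (`sample_id`, `feature_id`,
#'   `log_cpm`).
#' @param dosage Named dosage vector (names = sample ids).
#' @param features Optional subset of features to show.
#' @return A ggplot object.
#' @export
plot_dosage_expression <- function(exprs, dosage, features = NULL) {
  df <- exprs |>
    mutate(dosage = factor(round(unname(dosage[.data$sample_id])))) |>
    filter(is.null(features) | .data$feature_id %in% features)
  ggplot(df, aes(x = .data$dosage, y = .data$log_cpm)) +
    geom_boxplot(outlier.shape = NA) +
    geom_jitter(width = 0.15, alpha = 0.3, size = 0.6) +
    facet_wrap(~feature_id, scales = "free_y") +
    labs(x = "alt-allele dosage", y = "log2 CPM") +
    theme_minimal()
}

#' Plot an eQTL scan
#'
#' -log10 p-value per variant, faceted by expression feature, with effect
#' direction as colour.
#'
#' @param object An `eqtl_scan` tibble from [map_cis_eqtls()].
#' @param variants Optional variant tibble with `variant_id` and `pos` to
#'   place variants genomically; defaults to rank order.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eqtl_scan <- function(object, variants = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(variants)) {
    df <- df |> left_join(variants |> select("variant_id", "pos"),
                          by = "variant_id")
  } else {
    df <- df |> group_by(.data$feature_id) |> mutate(pos = row_number()) |> ungroup()
  }
  ggplot(df, aes(x = .data$pos, y = -log10(.data$p_value),
                 colour = .data$beta > 0)) +
    geom_point() +
    facet_wrap(~feature_id) +
    labs(x = "position", y = "-log10 p",
         colour = "beta > 0") +
    theme_minimal()
}

#' Plot a coexpression result
#'
#' Volcano-style view: correlation against -log10 adjusted p.
#'
#' @param object A `coexpr_result` tibble from [coexpression()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coexpr_result <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$r, y = -log10(.data$fdr_bh))) +
    geom_point(alpha = 0.6) +
    geom_hline(yintercept = -log10(0.05), linetype = 2) +
    labs(x = "Pearson r with target", y = "-log10 BH-adjusted p") +
    theme_minimal()
}

#' Plot gene-set enrichment results
#'
#' Normalized enrichment score per set, coloured by direction.
#'
#' @param object A `gsea_result` tibble from [gsea_preranked()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gsea_result <- function(object, ...) {
  df <- as_tibble(object) |> arrange(.data$es) |>
    mutate(set_id = factor(.data$set_id, levels = .data$set_id))
  ggplot(df, aes(x = .data$es, y = .data$set_id, colour = .data$direction)) +
    geom_point(aes(size = -log10(.data$p_value))) +
    labs(x = "enrichment score", y = NULL, size = "-log10 p") +
    theme_minimal()
}

#' GSEA running-sum plot for one gene set
#'
#' @param scores Named signed score vector (as passed to
#'   [gsea_preranked()]).
#' @param set Character vector of member gene ids.
#' @param weight_p Hit-weight exponent.
#' @return A ggplot object showing the running enrichment sum.
#' @export
plot_gsea_running_sum <- function(scores, set, weight_p = 1) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  in_set <- names(s) %in% set
  nh <- sum(in_set)
  hit_w <- abs(s)^weight_p * in_set
  hit_w <- if (sum(hit_w) == 0) in_set / nh else hit_w / sum(hit_w)
  running <- cumsum(hit_w - (!in_set) / (length(s) - nh))
  df <- tibble(rank = seq_along(running), running = running)
  ggplot(df, aes(x = .data$rank, y = .data$running)) +
    geom_line() +
    geom_hline(yintercept = 0, colour = "grey60") +
    labs(x = "gene rank", y = "running enrichment sum") +
    theme_minimal()
}
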