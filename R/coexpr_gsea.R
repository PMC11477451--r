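#' Genome-wide coexpression with a target gene
#'
#' Pearson correlation of every gene with the target on (optionally
#' covariate-adjusted) log-CPM, with the two-sided t-approximation p-value
#' `t = r sqrt(n - 2) / sqrt(1 - r^2)` and Benjamini-Hochberg adjustment.
#' The target is excluded from its own list; zero-variance genes are dropped
#' with a warning.
#'
#' @param exprs Long tibble (`sample_id`, `feature_id`, `log_cpm`) or a
#'   samples x genes matrix.
#' @param target Gene id to correlate against.
#' @param covariates Optional covariate tibble; when given, expression is
#'   residualized on the covariates before correlating.
#' @return A tibble of class `coexpr_result` (`gene_id`, `r`, `p_value`,
#'   `fdr_bh`), sorted by `abs(r)` descending.
#' @export
coexpression <- function(exprs, target, covariates = NULL) {
  m <- if (is.matrix(exprs)) exprs else counts_to_matrix(exprs, "log_cpm")
  if (!target %in% colnames(m)) abort(sprintf("target gene %s not in matrix", target))
  n <- nrow(m)
  if (n < 4L) abort("coexpression needs at least 4 samples")
  if (!is.null(covariates)) {
    X <- build_design(covariates, rownames(m))
    m <- stats::lm.fit(X, m)$residuals
  }
  v <- apply(m, 2, stats::var)
  if (any(v == 0)) {
    warn(sprintf("dropping %d zero-variance gene(s)", sum(v == 0)))
    m <- m[, v > 0, drop = FALSE]
  }
  if (!target %in% colnames(m)) abort("target gene has zero variance")
  others <- setdiff(colnames(m), target)
  r <- as.numeric(stats::cor(m[, target], m[, others, drop = FALSE]))
  tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p <- pmax(p, .Machine$double.xmin)
  out <- tibble(gene_id = others, r = r, p_value = p,
                fdr_bh = bh_fdr(p)) |>
    arrange(desc(abs(.data$r)))
  class(out) <- c("coexpr_result", class(out))
  out
}

#' Coexpressed gene list at an unadjusted p threshold
#'
#' @param coexpr A `coexpr_result` tibble.
#' @param p_max Unadjusted p-value cutoff (default 0.001).
#' @return The filtered rows.
#' @export
coexpression_hits <- function(coexpr, p_max = 0.001) {
  coexpr |> filter(.data$p_value < p_max)
}

#' Read gene sets from GMT
#'
#' @param path GMT file (set id, description, then member genes, tab
#'   separated).
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    warn(sprintf("dropping %d empty gene set(s)", sum(empty)))
    sets <- sets[!empty]
  }
  sets
}

# classic weighted Kolmogorov-Smirnov running-sum enrichment score
gsea_es <- function(score_sorted, in_set, weight_p = 1) {
  nh <- sum(in_set)
  n <- length(score_sorted)
  hit_w <- abs(score_sorted)^weight_p * in_set
  denom <- sum(hit_w)
  if (denom == 0) hit_w[in_set] <- 1 / nh else hit_w <- hit_w / denom
  miss <- (!in_set) / (n - nh)
  running <- cumsum(hit_w - miss)
  # ties in |deviation| (within 1e-9) break toward the earlier rank position
  idx <- which(abs(running) > max(abs(running)) - 1e-9)[1]
  unname(running[idx])
}

#' Preranked gene-set enrichment analysis
#'
#' Classic weighted Kolmogorov-Smirnov running-sum enrichment: genes are
#' ranked by a signed score (e.g. coexpression r); walking down the ranking,
#' set members increment the running sum by `|score|^weight_p` (normalized
#' over the set's hits) and non-members decrement it by `1/(N - Nh)`. The
#' enrichment score (ES) is the maximum deviation from zero. Significance
#' comes from gene-label permutations: random sets of the same size,
#' compared with the observed ES among permuted ES of the same sign. NES is
#' ES divided by the mean absolute permuted ES of the same sign. When two
#' positions of the running sum deviate equally (within 1e-9), the earlier
#' rank position defines the ES.
#'
#' @param scores Named numeric vector of signed per-gene scores (unique
#'   names), or a tibble with `gene_id` and `score` columns.
#' @param sets Named list of gene-id vectors (see [read_gmt()]).
#' @param n_perm Number of gene-label permutations; `0` skips the null
#'   (p and NES are `NA`).
#' @param weight_p Hit-weight exponent (1 = classic weighted, 0 =
#'   unweighted Kolmogorov-Smirnov).
#' @param seed Integer seed for the permutation null.
#' @param min_overlap Sets overlapping the ranked universe by fewer genes
#'   are skipped with a warning.
#' @return A tibble of class `gsea_result`: `set_id`, `size`, `es`, `nes`,
#'   `p_value`, `direction`.
#' @export
gsea_preranked <- function(scores, sets, n_perm = 1000, weight_p = 1,
                           seed = NULL, min_overlap = 1) {
  if (is.data.frame(scores)) {
    scores <- stats::setNames(scores$score, scores$gene_id)
  }
  if (anyDuplicated(names(scores))) abort("gene ids in the ranking must be unique")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  genes <- names(s)
  n <- length(s)
  if (!is.null(seed)) set.seed(seed)
  res <- map(names(sets), function(sid) {
    members <- intersect(sets[[sid]], genes)
    nh <- length(members)
    if (nh < min_overlap || nh == 0L || nh == n) {
      warn(sprintf("gene set %s skipped (overlap %d of %d)", sid, nh, n))
      return(NULL)
    }
    in_set <- genes %in% members
    es <- gsea_es(s, in_set, weight_p)
    if (n_perm > 0) {
      perm <- map_dbl(seq_len(n_perm), function(i) {
        gsea_es(s, genes %in% sample(genes, nh), weight_p)
      })
      same_sign <- perm[sign(perm) == sign(es)]
      pval <- (1 + sum(abs(same_sign) >= abs(es))) / (1 + length(same_sign))
      nes <- if (length(same_sign) > 0) es / mean(abs(same_sign)) else NA_real_
    } else {
      pval <- NA_real_; nes <- NA_real_
    }
    tibble(set_id = sid, size = nh, es = es, nes = nes, p_value = pval,
           direction = if (es >= 0) "positive" else "negative")
  }) |> list_rbind()
  class(res) <- c("gsea_result", class(res))
  res
}
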