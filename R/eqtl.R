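#' Read genotype dosages from VCF
#'
#' Dosages come from FORMAT/DS when present, otherwise from phased or
#' unphased GT collapsed to {0, 1, 2}. Imputation quality is read from
#' INFO/R2 (fallback INFO/INFO); minor allele frequency is recomputed from
#' the dosages of the analysis set.
#'
#' @param path VCF file.
#' @return A list with `variants` (tibble: `variant_id`, `chrom`, `pos`
#'   1-based, `ref`, `alt`, `maf`, `imputation_quality`) and `dosages`
#'   (numeric matrix, samples x variants).
#' @export
read_vcf_dosages <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ds <- tryCatch(vcfR::extract.gt(v, element = "DS", as.numeric = TRUE),
                 error = function(e) NULL)
  if (is.null(ds) || all(is.na(ds))) {
    gt <- vcfR::extract.gt(v, element = "GT")
    ds <- apply(gt, c(1, 2), function(g) {
      if (is.na(g)) return(NA_real_)
      sum(as.integer(strsplit(g, "[|/]")[[1]]))
    })
  }
  ds <- t(ds)  # samples x variants
  qual <- suppressWarnings(vcfR::extract.info(v, element = "R2", as.numeric = TRUE))
  if (is.null(qual) || all(is.na(qual))) {
    qual <- suppressWarnings(vcfR::extract.info(v, element = "INFO", as.numeric = TRUE))
  }
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  alt_freq <- colMeans(ds, na.rm = TRUE) / 2
  variants <- tibble(
    variant_id = fix$ID,
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    maf = unname(pmin(alt_freq, 1 - alt_freq)),
    imputation_quality = as.numeric(qual)
  )
  colnames(ds) <- variants$variant_id
  list(variants = variants, dosages = ds)
}

#' Filter variants to the cis window with MAF and quality thresholds
#'
#' Keeps variants positioned within `window_bp` of the gene span (boundary
#' inclusive on both sides) whose minor allele frequency and imputation
#' quality strictly exceed their thresholds.
#'
#' @param variants Variant tibble (`variant_id`, `pos`, `maf`,
#'   `imputation_quality`).
#' @param span One-row tibble or list with the locus `start` and `end`
#'   (0-based half-open genomic span, as from [gene_spans()]).
#' @param window_bp Cis window in bp around the span.
#' @param maf_min Strict lower bound on minor allele frequency.
#' @param qual_min Strict lower bound on imputation quality.
#' @return The surviving rows of `variants`.
#' @export
filter_cis_variants <- function(variants, span, window_bp = 500000,
                                maf_min = 0.05, qual_min = 0.8) {
  assert_cols(variants, c("variant_id", "pos", "maf", "imputation_quality"),
              "variant table")
  lo <- span$start - window_bp
  hi <- span$end + window_bp
  out <- variants |>
    filter(.data$pos >= lo, .data$pos <= hi,
           .data$maf > maf_min, .data$imputation_quality > qual_min)
  if (nrow(out) == 0L) message("no variants survive the cis filters")
  out
}

counts_to_matrix <- function(counts, value_col = "count") {
  assert_cols(counts, c("sample_id", "feature_id", value_col), "count table")
  wide <- counts |>
    select("sample_id", "feature_id", all_of(value_col)) |>
    pivot_wider(names_from = "feature_id", values_from = all_of(value_col)) |>
    arrange(.data$sample_id)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$sample_id
  m
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values between-sample scaling (Robinson-Oshlack), with
#' the standard trims (30% on log-ratios, 5% on average intensity), the
#' reference chosen as the sample whose upper quartile is closest to the
#' mean upper quartile, and factors scaled to geometric mean 1. The
#' computation is delegated to edgeR.
#'
#' @param counts Long tibble (`sample_id`, `feature_id`, `count`).
#' @param library_size Optional named vector of total mapped reads per
#'   sample; defaults to per-sample count sums. Library size is an input
#'   because mapped reads outside the modeled features still belong to it.
#' @return Tibble `sample_id`, `library_size`, `norm_factor`.
#' @export
tmm_factors <- function(counts, library_size = NULL) {
  m <- counts_to_matrix(counts)  # samples x features
  if (nrow(m) < 2L) abort("TMM needs at least two samples")
  zero <- rowSums(m) == 0
  if (any(zero)) {
    abort(sprintf("sample(s) with all-zero counts: %s",
                  paste(rownames(m)[zero], collapse = ", ")))
  }
  if (is.null(library_size)) {
    library_size <- rowSums(m)
  } else {
    library_size <- library_size[rownames(m)]
  }
  f <- edgeR::calcNormFactors(t(m), lib.size = unname(library_size),
                              method = "TMM")
  tibble(sample_id = rownames(m),
         library_size = unname(library_size),
         norm_factor = unname(f))
}

#' Log2 counts per million
#'
#' `log2((count + prior) / (library_size * factor + 2 * prior) * 1e6)`, the
#' voom-style log-CPM with a prior count making zeros finite.
#'
#' @param counts Long tibble (`sample_id`, `feature_id`, `count`).
#' @param factors Tibble from [tmm_factors()]; `NULL` means unit factors
#'   with library sizes from count sums.
#' @param prior_count Prior count added to the numerator (and doubled in the
#'   denominator).
#' @return Long tibble `sample_id`, `feature_id`, `log_cpm`.
#' @export
log_cpm <- function(counts, factors = NULL, prior_count = 0.5) {
  if (is.null(factors)) {
    factors <- counts |>
      group_by(.data$sample_id) |>
      summarise(library_size = sum(.data$count), .groups = "drop") |>
      mutate(norm_factor = 1)
  }
  stopifnot(all(factors$norm_factor > 0))
  counts |>
    inner_join(factors |> select("sample_id", "library_size", "norm_factor"),
               by = "sample_id") |>
    mutate(log_cpm = log2((.data$count + prior_count) /
                            (.data$library_size * .data$norm_factor + 2 * prior_count) * 1e6)) |>
    select("sample_id", "feature_id", "log_cpm")
}

#' Voom precision weights
#'
#' Fits per-feature linear models on log-CPM, lowess-smooths the
#' square-root residual standard deviation against mean log-count and
#' returns the predicted standard deviation to the power -4 as
#' per-observation weights (the voom recipe, via limma).
#'
#' @param counts Long tibble (`sample_id`, `feature_id`, `count`) over all
#'   expressed features (weights are calibrated on the genome-wide
#'   mean-variance trend).
#' @param design Design matrix or covariate tibble (rows = samples sorted by
#'   id); an intercept is added when absent.
#' @param factors Tibble from [tmm_factors()]; `NULL` for unit factors.
#' @param span Lowess span for the mean-variance trend.
#' @return Long tibble `sample_id`, `feature_id`, `weight` (all > 0).
#' @export
voom_weights <- function(counts, design = NULL, factors = NULL, span = 0.5) {
  m <- counts_to_matrix(counts)  # samples x features
  X <- build_design(design, rownames(m))
  if (ncol(m) < 10L) {
    warn("fewer than 10 features: falling back to unit voom weights")
    return(counts |> select("sample_id", "feature_id") |> mutate(weight = 1))
  }
  if (is.null(factors)) {
    lib <- rowSums(m); nf <- rep(1, nrow(m))
  } else {
    ord <- match(rownames(m), factors$sample_id)
    lib <- factors$library_size[ord]; nf <- factors$norm_factor[ord]
  }
  vm <- limma::voom(t(m), design = X, lib.size = lib * nf, span = span)
  w <- t(vm$weights)  # samples x features
  # residual-sd floor of 1e-4: zero-variance features otherwise blow up to
  # infinite precision weights
  w[!is.finite(w) | w > 1e16] <- 1e16
  w[w <= 0] <- .Machine$double.eps
  dimnames(w) <- dimnames(m)
  as_tibble(w, rownames = "sample_id") |>
    pivot_longer(-"sample_id", names_to = "feature_id", values_to = "weight")
}

build_design <- function(design, sample_ids) {
  n <- length(sample_ids)
  if (is.null(design)) return(matrix(1, n, 1, dimnames = list(sample_ids, "(Intercept)")))
  if (is.data.frame(design)) {
    if ("sample_id" %in% names(design)) {
      design <- design[match(sample_ids, design$sample_id), , drop = FALSE]
      design$sample_id <- NULL
    }
    design <- as.matrix(design)
  }
  stopifnot(nrow(design) == n)
  if (!any(apply(design, 2, function(x) all(x == 1)))) {
    design <- cbind(`(Intercept)` = 1, design)
  }
  if (qr(design)$rank < ncol(design)) abort("design matrix is rank deficient")
  rownames(design) <- sample_ids
  design
}

#' Residual principal components as expression surrogates
#'
#' Computes the top-k principal components of the expression matrix after
#' regressing out known covariates, playing the confounder-absorbing role of
#' surrogate variables. Component columns are unit-norm with a deterministic
#' sign convention (the largest-magnitude loading is positive). Compute the
#' components on genes OUTSIDE the cis locus under test, otherwise a strong
#' cis signal can be absorbed into a component and the dosage effect
#' shrunk toward zero.
#'
#' @param exprs Long tibble (`sample_id`, `feature_id`, `log_cpm`) or a
#'   samples x features matrix.
#' @param k Number of components; `k = 0` returns no columns.
#' @param covariates Optional covariate tibble/matrix to regress out first.
#' @return Tibble `sample_id`, `PC1` ... `PCk`.
#' @export
residual_pcs <- function(exprs, k, covariates = NULL) {
  m <- if (is.matrix(exprs)) exprs else counts_to_matrix(exprs, "log_cpm")
  if (k <= 0) return(tibble(sample_id = rownames(m)))
  if (k >= min(dim(m))) abort("k must be smaller than both matrix dimensions")
  X <- build_design(covariates, rownames(m))
  resid <- stats::lm.fit(X, m)$residuals
  pc <- stats::prcomp(resid, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    lo <- pc$rotation[, j]
    if (lo[which.max(abs(lo))] < 0) scores[, j] <- -scores[, j]
    scores[, j] <- scores[, j] / sqrt(sum(scores[, j]^2))
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  as_tibble(scores, rownames = "sample_id")
}

#' Fit a single-variant eQTL model
#'
#' Weighted least squares of one expression vector on an intercept, the
#' alt-allele dosage, and covariates. The dosage coefficient is the eQTL
#' effect (log2 expression change per alt allele); its two-sided t-test has
#' n - p degrees of freedom.
#'
#' @param expression Numeric expression vector (typically log-CPM).
#' @param dosage Numeric dosage vector in `[0, 2]`.
#' @param covariates Optional covariate matrix/tibble (no intercept needed).
#' @param weights Optional positive observation weights; `NULL` = OLS.
#' @param feature_id,variant_id Labels carried into the result.
#' @return An object of class `eqtl_fit`; see [tidy.eqtl_fit()] and
#'   [glance.eqtl_fit()].
#' @export
fit_eqtl <- function(expression, dosage, covariates = NULL, weights = NULL,
                     feature_id = "feature", variant_id = "variant") {
  n <- length(expression)
  stopifnot(length(dosage) == n)
  if (stats::var(dosage) == 0) {
    abort(sprintf("variant %s has no dosage variance (monomorphic)", variant_id))
  }
  X <- cbind(`(Intercept)` = 1, dosage = dosage)
  if (!is.null(covariates)) {
    cv <- if (is.data.frame(covariates)) {
      cv0 <- covariates
      cv0$sample_id <- NULL
      as.matrix(cv0)
    } else as.matrix(covariates)
    X <- cbind(X, cv)
  }
  p <- ncol(X)
  if (n < p + 2L) abort("too few samples for the requested model")
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(all(weights > 0))
  fit <- stats::lm.wfit(X, expression, w = weights)
  df <- n - p
  rss <- sum(weights * fit$residuals^2)
  sigma2 <- rss / df
  XtWX_inv <- chol2inv(chol(crossprod(X * sqrt(weights))))
  se <- stats::setNames(sqrt(diag(XtWX_inv) * sigma2), colnames(X))
  beta <- fit$coefficients
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), df = df, lower.tail = FALSE)
  structure(list(
    feature_id = feature_id, variant_id = variant_id,
    coefficients = tibble(term = colnames(X), estimate = unname(beta),
                          std.error = unname(se), statistic = unname(tval),
                          p.value = unname(pval)),
    beta = unname(beta["dosage"]), se = unname(se["dosage"]),
    t_stat = unname(tval["dosage"]), p_value = unname(pval["dosage"]),
    n = n, df = df, sigma = sqrt(sigma2),
    r_squared = 1 - rss / sum(weights * (expression - stats::weighted.mean(expression, weights))^2)
  ), class = "eqtl_fit")
}

#' @export
print.eqtl_fit <- function(x, ...) {
  cat(sprintf("eQTL fit: %s ~ %s  (n = %d)\n", x$feature_id, x$variant_id, x$n))
  cat(sprintf("  beta = %.4f  se = %.4f  t = %.2f  p = %.3g\n",
              x$beta, x$se, x$t_stat, x$p_value))
  invisible(x)
}

#' Tidy an eQTL fit
#'
#' @param x An `eqtl_fit` object.
#' @param ... Unused.
#' @return One row per model term with estimate, standard error, t statistic
#'   and p-value.
#' @export
tidy.eqtl_fit <- function(x, ...) {
  x$coefficients |> mutate(feature_id = x$feature_id, variant_id = x$variant_id)
}

#' One-row model summary of an eQTL fit
#'
#' @param x An `eqtl_fit` object.
#' @param ... Unused.
#' @return Tibble with the dosage effect, its test, model df and sigma.
#' @export
glance.eqtl_fit <- function(x, ...) {
  tibble(feature_id = x$feature_id, variant_id = x$variant_id,
         beta = x$beta, se = x$se, t_stat = x$t_stat, p_value = x$p_value,
         r.squared = x$r_squared, df.residual = x$df, sigma = x$sigma, nobs = x$n)
}

#' Benjamini-Hochberg FDR within families
#'
#' @param p Vector of p-values in (0, 1].
#' @param family Optional grouping vector; adjustment is applied within each
#'   family separately (e.g. per expression feature across its cis variants).
#' @return Adjusted values, same order as `p`.
#' @export
bh_fdr <- function(p, family = NULL) {
  stopifnot(all(p > 0 & p <= 1))
  if (is.null(family)) return(stats::p.adjust(p, method = "BH"))
  out <- numeric(length(p))
  for (f in unique(family)) {
    idx <- which(family == f)
    out[idx] <- stats::p.adjust(p[idx], method = "BH")
  }
  out
}

#' Map cis-eQTLs for all feature x variant pairs
#'
#' Runs [fit_eqtl()] for every expression feature against every variant and
#' adjusts p-values by Benjamini-Hochberg within each feature family.
#'
#' @param exprs Long tibble (`sample_id`, `feature_id`, `log_cpm`).
#' @param dosages Samples x variants dosage matrix (rownames = sample ids).
#' @param covariates Optional covariate tibble with `sample_id`.
#' @param weights Optional long weight tibble from [voom_weights()].
#' @return A tibble of class `eqtl_scan`: `feature_id`, `variant_id`,
#'   `beta`, `se`, `t_stat`, `p_value`, `fdr_bh`.
#' @export
map_cis_eqtls <- function(exprs, dosages, covariates = NULL, weights = NULL) {
  em <- counts_to_matrix(exprs, "log_cpm")
  stopifnot(!is.null(rownames(dosages)))
  dm <- dosages[rownames(em), , drop = FALSE]
  wm <- if (is.null(weights)) NULL else {
    w <- counts_to_matrix(weights, "weight")
    w[rownames(em), colnames(em), drop = FALSE]
  }
  res <- map(colnames(em), function(f) {
    map(colnames(dm), function(v) {
      fit <- fit_eqtl(em[, f], dm[, v], covariates = covariates,
                      weights = if (is.null(wm)) NULL else wm[, f],
                      feature_id = f, variant_id = v)
      glance(fit) |> select("feature_id", "variant_id", "beta", "se",
                            "t_stat", "p_value")
    }) |> list_rbind()
  }) |> list_rbind()
  res <- res |> mutate(fdr_bh = bh_fdr(.data$p_value, .data$feature_id))
  class(res) <- c("eqtl_scan", class(res))
  res
}
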