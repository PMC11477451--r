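#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom tidyr pivot_wider pivot_longer unnest
#' @importFrom purrr map map_dbl map_chr map_int map2 pmap imap list_rbind
NULL

# consistent text-file writing: LF endings, no scientific notation
write_lines_lf <- function(x, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(x, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

fmt_num <- function(x, digits = 6) {
  formatC(x, format = "g", digits = digits)
}

assert_cols <- function(df, cols, what = deparse(substitute(df))) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0L) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(miss, collapse = ", ")))
  }
  invisible(df)
}

# seeds derived from a master seed, kept inside 32-bit integer range.
# Two Lehmer-style multiplicative scrambles keep derived seeds far apart:
# adjacent offsets must not map to adjacent seeds, or the Mersenne-Twister
# streams they initialize are weakly correlated.
derive_seed <- function(seed, offset) {
  x <- as.numeric(seed) %% 2147483647
  x <- (x * 48271) %% 2147483647
  x <- (x + offset * 1103515245 + 12345) %% 2147483647
  x <- (x * 69621) %% 2147483647
  as.integer(x)
}
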