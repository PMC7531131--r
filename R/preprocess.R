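#' Remove abundant and lowly expressed genes from a count table
#'
#' Drops (i) every gene named in `abundant` (highly abundant contractile genes
#' such as myosins, tropomyosins and troponins dominate muscle libraries and
#' are removed by an explicit list), and (ii) every gene whose count is
#' `<= max_count` in at least `min_samples` samples. Remaining rows keep their
#' input order. The operation is idempotent.
#'
#' @param counts tibble with a `gene` column and one numeric column per sample.
#' @param abundant character vector of gene ids to drop (default none).
#' @param max_count low-count threshold (a gene "fails" a sample when its
#'   count is `<= max_count`).
#' @param min_samples number of failing samples at which a gene is removed.
#' @return filtered tibble, same columns.
#' @export
filter_genes <- function(counts, abundant = character(),
                         max_count = 5, min_samples = 9) {
  m <- expr_matrix(counts, "counts")
  if (min_samples > ncol(m)) {
    abort("min_samples exceeds the number of samples")
  }
  low <- rowSums(m <= max_count) >= min_samples
  drop <- low | rownames(m) %in% abundant
  if (all(drop)) warn("filter_genes() removed every gene")
  counts[!drop, , drop = FALSE]
}

# Reference sample: the one whose 75th count quantile (scaled by library
# size) is closest to the mean across samples.
tmm_ref_sample <- function(m) {
  lib <- colSums(m)
  f75 <- apply(m, 2, quantile, probs = 0.75) / lib
  colnames(m)[which.min(abs(f75 - mean(f75)))]
}

# Single-pair TMM factor: weighted trimmed mean of M-values of `obs` against
# `ref`, trimming 30% of M-values and 5% of A-values from each tail; genes
# with a zero count in either sample are excluded.
tmm_pair_factor <- function(obs, ref, trim_m = 0.30, trim_a = 0.05) {
  n_o <- sum(obs)
  n_r <- sum(ref)
  log_r <- log2((obs / n_o) / (ref / n_r))            # M-values
  abs_e <- (log2(obs / n_o) + log2(ref / n_r)) / 2    # A-values
  v <- (n_o - obs) / (n_o * obs) + (n_r - ref) / (n_r * ref)  # asymptotic var
  fin <- is.finite(log_r) & is.finite(abs_e)
  log_r <- log_r[fin]; abs_e <- abs_e[fin]; v <- v[fin]
  if (length(log_r) == 0 || max(abs(log_r)) < 1e-6) return(1)
  n <- length(log_r)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  keep <- rank(log_r) >= lo_m & rank(log_r) <= hi_m &
    rank(abs_e) >= lo_a & rank(abs_e) <= hi_a
  f <- sum(log_r[keep] / v[keep]) / sum(1 / v[keep])
  if (!is.finite(f)) f <- 0
  2^f
}

#' Trimmed-mean-of-M-values (TMM) normalization factors
#'
#' Computes one scaling factor per sample as `2^(weighted trimmed mean of
#' per-gene M-values against a reference sample)`, trimming 30% of M-values
#' and 5% of A-values from each tail and weighting by inverse asymptotic
#' variance. Factors are rescaled so their geometric mean is 1. The effective
#' library size is `total counts x factor`.
#'
#' @param counts tibble with a `gene` column and one numeric count column per
#'   sample (post-filtering).
#' @param ref_sample reference sample id, or `NULL` to pick the sample whose
#'   upper-quartile expression is closest to the mean upper quartile.
#' @return tibble: `sample`, `lib_size`, `tmm_factor`, `eff_lib_size`.
#' @export
tmm_factors <- function(counts, ref_sample = NULL) {
  m <- expr_matrix(counts, "counts")
  lib <- colSums(m)
  if (any(lib <= 0)) abort("every sample must have a positive total count")
  ref_sample <- ref_sample %||% tmm_ref_sample(m)
  if (!ref_sample %in% colnames(m)) abort("unknown ref_sample")
  f <- vapply(colnames(m), function(s) {
    tmm_pair_factor(m[, s], m[, ref_sample])
  }, numeric(1))
  f[!is.finite(f)] <- 1
  f <- f / exp(mean(log(f)))  # geometric mean 1
  tibble(
    sample = colnames(m), lib_size = unname(lib),
    tmm_factor = unname(f), eff_lib_size = unname(lib * f)
  )
}

#' TMM-normalized log2 counts-per-million
#'
#' Applies [tmm_factors()] and returns expression on the log2-CPM scale with
#' a small prior count to keep zeros finite:
#' `log2((count + prior) / (eff_lib_size + 2 * prior) * 1e6)`.
#'
#' @inheritParams tmm_factors
#' @param prior_count prior added to each count before the log.
#' @return object of class `normalized_expr`: list with `log_cpm` (tibble,
#'   `gene` + sample columns) and `samples` (the [tmm_factors()] tibble).
#' @export
normalize_counts <- function(counts, ref_sample = NULL, prior_count = 0.5) {
  m <- expr_matrix(counts, "counts")
  fac <- tmm_factors(counts, ref_sample)
  eff <- fac$eff_lib_size[match(colnames(m), fac$sample)]
  lc <- log2(sweep(m + prior_count, 2, eff + 2 * prior_count, "/") * 1e6)
  structure(
    list(log_cpm = expr_tibble(lc), samples = fac, prior_count = prior_count),
    class = "normalized_expr"
  )
}

#' @export
print.normalized_expr <- function(x, ...) {
  cat(sprintf(
    "TMM-normalized expression: %d genes x %d samples (log2 CPM, prior %.2g)\n",
    nrow(x$log_cpm), ncol(x$log_cpm) - 1L, x$prior_count
  ))
  print(x$samples)
  invisible(x)
}

# Accept a normalized_expr, a tibble with `gene`, or a matrix.
values_matrix <- function(expr, arg = "expr") {
  if (inherits(expr, "normalized_expr")) return(expr_matrix(expr$log_cpm))
  expr_matrix(expr, arg)
}

#' Keep the most variable genes
#'
#' Retains the `ceiling(fraction * n_genes)` genes with the largest
#' across-sample variance of log2-CPM values. Ties are broken by gene id
#' (lexicographic) for determinism.
#'
#' @param expr a `normalized_expr` or a tibble with a `gene` column.
#' @param fraction fraction of genes to keep, in (0, 1].
#' @return same type as `expr`, restricted to the selected genes.
#' @export
select_variable_genes <- function(expr, fraction = 0.5) {
  if (fraction <= 0 || fraction > 1) abort("fraction must be in (0, 1]")
  m <- values_matrix(expr)
  v <- apply(m, 1, var)
  keep_n <- ceiling(fraction * nrow(m))
  ord <- order(-v, rownames(m))
  keep <- sort(ord[seq_len(keep_n)])  # preserve input order
  if (inherits(expr, "normalized_expr")) {
    expr$log_cpm <- expr$log_cpm[keep, , drop = FALSE]
    expr
  } else {
    expr[keep, , drop = FALSE]
  }
}
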