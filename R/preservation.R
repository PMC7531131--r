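# Module preservation: does a reference-condition module keep its density and
# connectivity pattern in a test condition? Twelve statistics (6 density + 6
# connectivity) are standardized against a permutation null in which module
# labels are reassigned to random gene sets of the same size.

density_stat_names <- c(
  "meanSignAwareCorDat", "meanAdj", "propVarExplained",
  "meanSignAwareKME", "meanClusterCoeff", "meanMAR"
)
connectivity_stat_names <- c(
  "cor.kIM", "cor.kME", "cor.cor", "cor.clusterCoeff", "cor.MAR", "cor.Adj"
)

# clustering coefficient and maximum adjacency ratio for a (sub)adjacency
cluster_coeff <- function(a) {
  a0 <- a; diag(a0) <- 0
  num <- diag(a0 %*% a0 %*% a0)
  den <- rowSums(a0)^2 - rowSums(a0^2)
  ifelse(den > .Machine$double.eps, num / den, 0)
}

max_adj_ratio <- function(a) {
  a0 <- a; diag(a0) <- 0
  s <- rowSums(a0)
  ifelse(s > .Machine$double.eps, rowSums(a0^2) / s, 0)
}

# first right-singular vector of a standardized gene x sample block,
# sign-aligned with the mean standardized profile
block_eigengene <- function(xs) {
  sv <- svd(xs, nu = 0, nv = 1)
  v1 <- sv$v[, 1]
  if (sum(v1 * colMeans(xs)) < 0) v1 <- -v1
  list(v = v1, pve = sv$d[1]^2 / sum(sv$d^2))
}

# The 12-statistic panel. The reference side is always evaluated on the
# module's own genes (idx_ref); the test side on idx_test — the same genes
# for the observed statistics, a random same-size gene set under the
# permutation null (labels reassigned in the test data only, paired by
# position).
preservation_stats_one <- function(idx_ref, idx_test, env) {
  rr <- env$cor_ref[idx_ref, idx_ref]
  rt <- env$cor_test[idx_test, idx_test]
  ar <- env$adj_ref[idx_ref, idx_ref]
  at <- env$adj_test[idx_test, idx_test]
  lt <- lower.tri(rr)

  me_r <- block_eigengene(env$xs_ref[idx_ref, , drop = FALSE])
  me_t <- block_eigengene(env$xs_test[idx_test, , drop = FALSE])
  kme_r <- as.vector(cor(t(env$m_ref[idx_ref, , drop = FALSE]), me_r$v))
  kme_t <- as.vector(cor(t(env$m_test[idx_test, , drop = FALSE]), me_t$v))

  kim_r <- rowSums(ar) - 1
  kim_t <- rowSums(at) - 1
  cc_r <- cluster_coeff(ar)
  cc_t <- cluster_coeff(at)
  mar_r <- max_adj_ratio(ar)
  mar_t <- max_adj_ratio(at)

  safe_cor <- function(x, y) {
    if (sd(x) == 0 || sd(y) == 0) return(0)
    cor(x, y)
  }

  c(
    meanSignAwareCorDat = mean(sign(rr[lt]) * rt[lt]),
    meanAdj = mean(at[lt]),
    propVarExplained = me_t$pve,
    meanSignAwareKME = mean(sign(kme_r) * kme_t),
    meanClusterCoeff = mean(cc_t),
    meanMAR = mean(mar_t),
    cor.kIM = safe_cor(kim_r, kim_t),
    cor.kME = safe_cor(kme_r, kme_t),
    cor.cor = safe_cor(rr[lt], rt[lt]),
    cor.clusterCoeff = safe_cor(cc_r, cc_t),
    cor.MAR = safe_cor(mar_r, mar_t),
    cor.Adj = safe_cor(ar[lt], at[lt])
  )
}

#' Permutation test of module preservation between two conditions
#'
#' For each reference module, computes six density statistics (how strongly
#' connected the module's genes remain in the test condition) and six
#' connectivity statistics (how well per-gene network quantities correlate
#' between conditions within the module), then standardizes each against a
#' permutation null in which module labels are reassigned to random gene sets
#' of the same size. Composites: `Z_density` and `Z_connectivity` are medians
#' of the respective Z scores, `Z_summary` their mean; `medianRank` is the
#' mean of the density and connectivity median ranks of observed statistics
#' across modules (rank 1 = most preserved). Modules are classified
#' `unpreserved` (`Z_summary <= 2` and `medianRank > n_modules / 2`),
#' `strong` (`Z_summary > 10`), or `weak_moderate` otherwise.
#'
#' @param ref_expr,test_expr `normalized_expr` objects or tibbles with a
#'   `gene` column (log2-CPM scale); gene sets are intersected.
#' @param modules tibble `gene`, `module`; `"grey"` background genes
#'   participate in the permutation pool but are not scored as a module.
#' @param power soft-thresholding power used for both conditions' adjacency.
#' @param n_perm number of permutations (2000 for full runs; reducible for
#'   quick checks).
#' @param seed optional integer for a reproducible null.
#' @param min_shared modules with fewer shared genes are flagged and skipped.
#' @return object of class `module_preservation`: list with `stats` (long
#'   tibble: module, size, statistic, type, observed, perm_mean, perm_sd, z),
#'   `summary` (module, size, z_density, z_connectivity, z_summary,
#'   median_rank, class), `skipped`, `n_perm`.
#' @export
module_preservation <- function(ref_expr, test_expr, modules, power,
                                n_perm = 2000, seed = NULL, min_shared = 3) {
  if (n_perm < 2) abort("n_perm must be >= 2")
  m_ref <- values_matrix(ref_expr, "ref_expr")
  m_test <- values_matrix(test_expr, "test_expr")
  shared <- intersect(rownames(m_ref), rownames(m_test))
  shared <- intersect(shared, modules$gene)
  if (length(shared) < 10) abort("fewer than 10 shared genes")
  dropped <- nrow(modules) - length(shared)
  if (dropped > 0) {
    inform(sprintf("%d genes absent from one condition were dropped", dropped))
  }
  m_ref <- m_ref[shared, , drop = FALSE]
  m_test <- m_test[shared, , drop = FALSE]
  lab <- modules$module[match(shared, modules$gene)]

  mods <- setdiff(sort(unique(lab)), "grey")
  sizes <- vapply(mods, function(mm) sum(lab == mm), integer(1))
  skipped <- mods[sizes < min_shared]
  if (length(skipped)) {
    warn(sprintf("module(s) with < %d shared genes skipped: %s",
                 min_shared, paste(skipped, collapse = ", ")))
  }
  mods <- mods[sizes >= min_shared]
  if (!length(mods)) abort("no testable modules")
  sizes <- sizes[mods]

  standardize <- function(m) {
    (m - rowMeans(m)) / apply(m, 1, sd)
  }
  env <- list(
    m_ref = m_ref, m_test = m_test,
    xs_ref = standardize(m_ref), xs_test = standardize(m_test),
    cor_ref = row_cor(m_ref), cor_test = row_cor(m_test)
  )
  env$adj_ref <- abs(env$cor_ref)^power; diag(env$adj_ref) <- 1
  env$adj_test <- abs(env$cor_test)^power; diag(env$adj_test) <- 1

  idx_of <- lapply(mods, function(mm) which(lab == mm))
  names(idx_of) <- mods
  observed <- vapply(idx_of, function(ix) {
    preservation_stats_one(ix, ix, env)
  }, numeric(12))
  # observed: 12 x n_modules

  if (!is.null(seed)) set.seed(seed)
  n <- length(shared)
  sums <- matrix(0, 12, length(mods))
  sq <- matrix(0, 12, length(mods))
  for (p in seq_len(n_perm)) {
    perm <- sample.int(n)
    for (j in seq_along(mods)) {
      s <- preservation_stats_one(idx_of[[j]], perm[idx_of[[j]]], env)
      sums[, j] <- sums[, j] + s
      sq[, j] <- sq[, j] + s^2
    }
  }
  perm_mean <- sums / n_perm
  perm_sd <- sqrt(pmax((sq - n_perm * perm_mean^2) / (n_perm - 1), 0))
  z <- (observed - perm_mean) / perm_sd
  z[perm_sd == 0] <- Inf  # flagged: no permutation variability

  stat_names <- rownames(observed)
  stats <- list_rbind(map(seq_along(mods), function(j) {
    tibble(
      module = mods[j], size = sizes[j], statistic = stat_names,
      type = ifelse(stat_names %in% density_stat_names, "density", "connectivity"),
      observed = unname(observed[, j]), perm_mean = unname(perm_mean[, j]),
      perm_sd = unname(perm_sd[, j]), z = unname(z[, j])
    )
  }))

  summary <- preservation_composites(stats)
  structure(
    list(stats = stats, summary = summary, skipped = skipped, n_perm = n_perm),
    class = "module_preservation"
  )
}

#' Composite preservation scores from the per-statistic table
#'
#' `Z_density`/`Z_connectivity` are medians of the density/connectivity Z
#' scores (non-finite Z values, flagged upstream, are excluded);
#' `Z_summary` is their mean. For `medianRank`, modules are ranked on each
#' observed statistic (rank 1 = most preserved, ties averaged); the median
#' rank is taken within each statistic type and the two medians averaged.
#'
#' @param stats long statistic tibble as produced by [module_preservation()]
#'   (columns `module`, `size`, `statistic`, `type`, `observed`, `z`).
#' @return tibble: `module`, `size`, `z_density`, `z_connectivity`,
#'   `z_summary`, `median_rank`, `class`.
#' @export
preservation_composites <- function(stats) {
  ranked <- stats %>%
    group_by(.data$statistic) %>%
    mutate(stat_rank = rank(-.data$observed, ties.method = "average")) %>%
    ungroup()
  out <- ranked %>%
    group_by(.data$module, .data$size) %>%
    summarise(
      z_density = median(.data$z[.data$type == "density"&
                                   is.finite(.data$z)]),
      z_connectivity = median(.data$z[.data$type == "connectivity" &
                                        is.finite(.data$z)]),
      median_rank = (median(.data$stat_rank[.data$type == "density"]) +
                       median(.data$stat_rank[.data$type == "connectivity"])) / 2,
      .groups = "drop"
    ) %>%
    mutate(z_summary = (.data$z_density + .data$z_connectivity) / 2)
  n_modules <- nrow(out)
  out %>%
    mutate(class = classify_module(.data$z_summary, .data$median_rank,
                                   n_modules)) %>%
    select("module", "size", "z_density", "z_connectivity", "z_summary",
           "median_rank", "class")
}

#' Classify module preservation
#'
#' `unpreserved` when `z_summary <= 2` and `median_rank > n_modules / 2`
#' (strict); `strong` when `z_summary > 10`; otherwise `weak_moderate`.
#'
#' @param z_summary,median_rank composite scores (vectorized).
#' @param n_modules total number of modules scored.
#' @return character vector of classes.
#' @export
classify_module <- function(z_summary, median_rank, n_modules) {
  if (n_modules < 1) abort("n_modules must be >= 1")
  ifelse(
    z_summary > 10, "strong",
    ifelse(z_summary <= 2 & median_rank > n_modules / 2,
           "unpreserved", "weak_moderate")
  )
}

#' @export
print.module_preservation <- function(x, ...) {
  cat(sprintf("Module preservation (%d permutations)\n", x$n_perm))
  print(x$summary)
  invisible(x)
}
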