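# Shared fixture builders (all generated in code; no stored data).

# small deterministic count tibble: genes x samples
toy_counts <- function(n_genes = 20, n_samples = 6, seed = 1, lambda = 50) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_samples, lambda), n_genes)
  rownames(m) <- sprintf("g%03d", seq_len(n_genes))
  colnames(m) <- sprintf("s%02d", seq_len(n_samples))
  dplyr::bind_cols(tibble::tibble(gene = rownames(m)),
                   tibble::as_tibble(as.data.frame(m)))
}

# expression tibble from an explicit matrix
expr_from_matrix <- function(m) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(gene = rownames(m)),
                   tibble::as_tibble(as.data.frame(m)))
}

# truth labels (0 = background) -> module tibble with grey/M<k> labels
truth_modules <- function(truth_genes) {
  tibble::tibble(
    gene = truth_genes$gene,
    module = ifelse(truth_genes$module == 0, "grey",
                    paste0("M", truth_genes$module))
  )
}

# adjusted Rand index (Hubert & Arabie) computed from the contingency table;
# independent of any clustering package
rand_index_adj <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_i * sum_j / n
  (sum_ij - expected) / ((sum_i + sum_j) / 2 - expected)
}

# small planted-module expression design used across network tests
planted_expr <- function(seed, n_samples = 20, perturbed = integer(),
                         n_modules = 6, module_size = 50, n_background = 300,
                         ...) {
  cfg <- sim_config(
    n_genes = n_modules * module_size + n_background,
    module_sizes = rep(module_size, n_modules),
    n_samples_a = n_samples, n_samples_b = n_samples,
    perturbed_modules = perturbed, seed = seed, ...
  )
  generate_expression(cfg)
}
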