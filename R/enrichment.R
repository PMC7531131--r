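#' Read gene-set collections from GMT files
#'
#' Standard GMT layout: one set per line, tab-separated
#' `set_id<TAB>description<TAB>gene1<TAB>gene2...`. The database tag is taken
#' from the file name (without extension).
#'
#' @param paths one or more GMT file paths.
#' @return tibble: `set_id`, `set_name`, `db`, `gene` (one row per member;
#'   duplicate members within a set are dropped).
#' @export
read_gmt <- function(paths) {
  out <- map(paths, function(p) {
    db <- sub("\\.gmt$", "", basename(p))
    lines <- readLines(p)
    lines <- lines[nzchar(lines)]
    rows <- map(lines, function(ln) {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(f) < 3) return(NULL)
      tibble(set_id = f[1], set_name = f[2], db = db,
             gene = unique(f[-(1:2)]))
    })
    list_rbind(rows)
  })
  list_rbind(out)
}

#' Hypergeometric overrepresentation test of a gene list against gene sets
#'
#' For every set, the one-sided overrepresentation p-value is
#' `P(X >= n_overlap)` under the hypergeometric distribution with the
#' analyzed-gene universe as the urn:
#' `p = sum_{k >= n_overlap} C(K,k) C(N-K, m-k) / C(N,m)` with `N` the
#' universe size, `K` the set size within the universe, and `m` the module
#' size. This equals a one-sided Fisher's exact test on the 2x2 overlap
#' table. Benjamini-Hochberg adjusted p-values are appended as an extra
#' column (`p_adjust`); the primary reported value is the raw Fisher p.
#'
#' @param module_genes character vector, a subset of `universe`.
#' @param universe character vector of analyzed genes (the network-analysis
#'   background, not the whole annotation).
#' @param gene_sets tibble from [read_gmt()] (columns `set_id`, `set_name`,
#'   `db`, `gene`).
#' @return tibble sorted by p-value: `set_id`, `set_name`, `db`,
#'   `n_universe`, `n_set`, `n_module`, `n_overlap`, `p_value`, `p_adjust`,
#'   `overlap_genes` (comma-separated).
#' @export
fisher_enrich <- function(module_genes, universe, gene_sets) {
  universe <- unique(universe)
  if (!length(universe)) abort("empty universe")
  module_genes <- unique(module_genes)
  if (!all(module_genes %in% universe)) {
    abort("module_genes must be a subset of universe")
  }
  gs <- gene_sets[gene_sets$gene %in% universe, ]
  dropped <- setdiff(unique(gene_sets$set_id), unique(gs$set_id))
  if (length(dropped)) {
    inform(sprintf("%d set(s) empty after intersecting with the universe",
                   length(dropped)))
  }
  n_univ <- length(universe)
  m <- length(module_genes)
  rows <- gs %>%
    group_by(.data$set_id, .data$set_name, .data$db) %>%
    summarise(
      n_set = n(),
      n_overlap = sum(.data$gene %in% module_genes),
      overlap_genes = paste(sort(.data$gene[.data$gene %in% module_genes]),
                            collapse = ","),
      .groups = "drop"
    ) %>%
    mutate(
      n_universe = n_univ, n_module = m,
      p_value = phyper(.data$n_overlap - 1, .data$n_set,
                       n_univ - .data$n_set, m, lower.tail = FALSE),
      p_adjust = p.adjust(.data$p_value, method = "BH")
    ) %>%
    arrange(.data$p_value) %>%
    select("set_id", "set_name", "db", "n_universe", "n_set", "n_module",
           "n_overlap", "p_value", "p_adjust", "overlap_genes")
  rows
}
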