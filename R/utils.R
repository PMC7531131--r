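# Internal helpers shared across modules.

# Convert a gene-by-sample data frame (first column `gene`, remaining columns
# numeric samples) to a numeric matrix with gene rownames. Accepts a matrix
# with rownames unchanged.
expr_matrix <- function(x, arg = "x") {
  if (is.matrix(x)) {
    if (is.null(rownames(x))) abort(sprintf("`%s` matrix must have gene rownames", arg))
    return(x)
  }
  if (!is.data.frame(x)) abort(sprintf("`%s` must be a data frame or matrix", arg))
  if (!"gene" %in% names(x)) abort(sprintf("`%s` must have a `gene` column", arg))
  genes <- as.character(x$gene)
  if (anyDuplicated(genes)) abort(sprintf("duplicate gene identifiers in `%s`", arg))
  m <- as.matrix(x[setdiff(names(x), "gene")])
  if (!is.numeric(m)) abort(sprintf("sample columns of `%s` must be numeric", arg))
  rownames(m) <- genes
  m
}

# Inverse of expr_matrix(): matrix -> tibble with a `gene` column.
expr_tibble <- function(m) {
  bind_cols(tibble(gene = rownames(m)), as_tibble(m, .name_repair = "minimal"))
}

# Lower-triangle (i > j) of a square matrix as a vector, fixed order.
lower_vec <- function(m) m[lower.tri(m)]

# Pearson correlation matrix across rows (genes); errors on zero-variance rows.
row_cor <- function(m, check = TRUE) {
  if (check) {
    v <- apply(m, 1, var)
    bad <- which(v == 0 | !is.finite(v))
    if (length(bad)) {
      abort(sprintf(
        "zero-variance gene(s): %s",
        paste(head(rownames(m)[bad], 5), collapse = ", ")
      ))
    }
  }
  cor(t(m))
}

`%||%` <- rlang::`%||%`
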