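# Plain-text readers/writers for the pipeline's tabular formats.

#' Write / read a gene-by-sample count or expression table (TSV)
#'
#' First column `gene`, remaining columns one per sample.
#'
#' @param x tibble with a `gene` column.
#' @param path file path.
#' @export
write_counts_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  as_tibble(read.delim(path, check.names = FALSE, stringsAsFactors = FALSE))
}

#' Write / read synthetic gene models (BED12-like TSV)
#'
#' One row per gene: `gene`, `chrom`, `strand`, `start`, `end`,
#' comma-separated `exon_starts`/`exon_ends`, and the regulatory window
#' `reg_start`/`reg_end`. Coordinates are 1-based inclusive.
#'
#' @param genes gene-model tibble from [generate_annotation()].
#' @param path file path.
#' @export
write_gene_models <- function(genes, path) {
  write.table(genes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_models
#' @export
read_gene_models <- function(path) {
  g <- as_tibble(read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                            colClasses = c(exon_starts = "character",
                                           exon_ends = "character")))
  g$start <- as.integer(g$start); g$end <- as.integer(g$end)
  g$reg_start <- as.integer(g$reg_start); g$reg_end <- as.integer(g$reg_end)
  g
}

#' Expand gene models into per-interval rows
#'
#' @param genes gene-model tibble.
#' @return tibble with `gene`, `feature` (exon/intron/regulatory), `start`,
#'   `end`.
#' @export
gene_model_intervals <- function(genes) {
  rows <- pmap(genes, function(gene, chrom, strand, start, end,
                               exon_starts, exon_ends, reg_start, reg_end, ...) {
    es <- as.integer(strsplit(exon_starts, ",")[[1]])
    ee <- as.integer(strsplit(exon_ends, ",")[[1]])
    ex <- tibble(gene = gene, feature = "exon", start = es, end = ee)
    intr <- if (length(es) > 1L) {
      tibble(gene = gene, feature = "intron",
             start = ee[-length(ee)] + 1L, end = es[-1] - 1L)
    } else NULL
    reg <- tibble(gene = gene, feature = "regulatory",
                  start = reg_start, end = reg_end)
    bind_rows(ex, intr, reg)
  })
  list_rbind(rows)
}

#' Write / read Bismark-style cytosine reports (one file per sample)
#'
#' Columns per file: chromosome, 1-based position, strand, count methylated,
#' count unmethylated, context.
#'
#' @param cytosines long cytosine tibble (as from [generate_methylation()]).
#' @param dir output directory; files are named `<sample>.CpG_report.txt`.
#' @export
write_cytosine_reports <- function(cytosines, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  for (s in unique(cytosines$sample)) {
    d <- cytosines[cytosines$sample == s,
                   c("chrom", "pos", "strand", "count_methylated",
                     "count_unmethylated", "context")]
    p <- file.path(dir, paste0(s, ".CpG_report.txt"))
    write.table(d, p, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @rdname write_cytosine_reports
#' @param files named character vector of report paths (names = sample ids).
#' @param groups tibble with columns `sample`, `group`.
#' @export
read_cytosine_reports <- function(files, groups) {
  if (is.null(names(files))) {
    names(files) <- sub("\\.CpG_report\\.txt$", "", basename(files))
  }
  out <- imap(files, function(p, s) {
    d <- read.delim(p, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("chrom", "pos", "strand",
                                  "count_methylated", "count_unmethylated",
                                  "context"))
    d$sample <- s
    as_tibble(d)
  })
  out <- list_rbind(out)
  left_join(out, groups, by = "sample")
}
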