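# Differential methylation from per-cytosine per-sample counts, genomic
# region assignment, and per-gene methylation levels.

#' Filter evaluable cytosines
#'
#' Keeps cytosines of the requested context. Within a cytosine, sample
#' records with coverage below `min_coverage` are dropped; the cytosine is
#' retained only when at least `min_samples_per_group` samples survive in
#' each group (this guarantees a testable design for the logistic
#' regression).
#'
#' @param cytosines long tibble: `chrom`, `pos`, `strand`, `context`,
#'   `sample`, `group`, `count_methylated`, `count_unmethylated`.
#' @param min_coverage minimum read coverage (methylated + unmethylated) for
#'   a sample record to count (boundary inclusive: coverage 8 passes at the
#'   default).
#' @param context retained context label.
#' @param min_samples_per_group minimum surviving samples per group.
#' @return filtered tibble, same columns.
#' @export
filter_cytosines <- function(cytosines, min_coverage = 8, context = "CpG",
                             min_samples_per_group = 3) {
  d <- cytosines[cytosines$context == context, , drop = FALSE]
  cov <- d$count_methylated + d$count_unmethylated
  d <- d[cov >= min_coverage, , drop = FALSE]
  if (!nrow(d)) return(d)
  keep <- d %>%
    group_by(.data$chrom, .data$pos, .data$strand) %>%
    summarise(
      ok = sum(.data$group == "A") >= min_samples_per_group &
        sum(.data$group == "B") >= min_samples_per_group,
      .groups = "drop"
    ) %>%
    filter(.data$ok)
  inner_join(d, select(keep, -"ok"), by = c("chrom", "pos", "strand"))
}

#' Test cytosines for differential methylation between groups
#'
#' Per cytosine, a binomial logistic regression of methylation proportion on
#' group is tested against the intercept-only model by likelihood-ratio test
#' (chi-squared, 1 df). With a single two-level factor the maximum-likelihood
#' fit is the pooled (coverage-weighted) proportion within each group, so the
#' deviance difference is evaluated in closed form; this is exactly the
#' `glm(cbind(meth, unmeth) ~ group, family = binomial)` likelihood-ratio
#' test. q-values are Benjamini-Hochberg adjusted over all tested cytosines.
#' A differentially methylated cytosine (DMC) has
#' `|delta_percent| > delta_cut` and `q_value <= q_cut`.
#'
#' @param cytosines filtered long tibble from [filter_cytosines()].
#' @param delta_cut minimum absolute methylation change, percent (strict
#'   inequality).
#' @param q_cut maximum q-value (inclusive).
#' @return tibble: `chrom`, `pos`, `strand`, `prop_a`, `prop_b`,
#'   `delta_percent` (B - A, x100), `p_value`, `q_value`, `is_dmc`,
#'   `separation` (one group fully methylated, the other fully
#'   unmethylated).
#' @export
dm_test <- function(cytosines, delta_cut = 20, q_cut = 0.10) {
  agg <- cytosines %>%
    group_by(.data$chrom, .data$pos, .data$strand) %>%
    summarise(
      y_a = sum(.data$count_methylated[.data$group == "A"]),
      n_a = sum((.data$count_methylated + .data$count_unmethylated)[.data$group == "A"]),
      y_b = sum(.data$count_methylated[.data$group == "B"]),
      n_b = sum((.data$count_methylated + .data$count_unmethylated)[.data$group == "B"]),
      .groups = "drop"
    )
  if (any(agg$n_a == 0 | agg$n_b == 0)) {
    abort("every tested cytosine needs coverage in both groups; run filter_cytosines() first")
  }
  # binomial log-likelihood contribution with 0*log(0) = 0
  ll <- function(y, n, p) {
    t1 <- ifelse(y > 0, y * log(p), 0)
    t2 <- ifelse(n - y > 0, (n - y) * log(1 - p), 0)
    t1 + t2
  }
  pa <- agg$y_a / agg$n_a
  pb <- agg$y_b / agg$n_b
  p0 <- (agg$y_a + agg$y_b) / (agg$n_a + agg$n_b)
  lrt <- 2 * (ll(agg$y_a, agg$n_a, pa) + ll(agg$y_b, agg$n_b, pb) -
                ll(agg$y_a, agg$n_a, p0) - ll(agg$y_b, agg$n_b, p0))
  lrt <- pmax(lrt, 0)
  p <- pchisq(lrt, df = 1, lower.tail = FALSE)
  q <- p.adjust(p, method = "BH")
  delta <- (pb - pa) * 100
  tibble(
    chrom = agg$chrom, pos = agg$pos, strand = agg$strand,
    prop_a = pa, prop_b = pb, delta_percent = delta,
    p_value = p, q_value = q,
    is_dmc = abs(delta) > delta_cut & q <= q_cut,
    separation = (pa == 0 & pb == 1) | (pa == 1 & pb == 0)
  )
}

#' Assign cytosines to genomic regions
#'
#' A position is `body` when it falls within a gene span (exons and introns),
#' `regulatory` when inside a gene's 5.5-kb upstream window (strand-aware:
#' upstream of the start for `+` genes, of the end for `-` genes), and
#' `intergenic` otherwise. A cytosine overlapping several genes' features is
#' annotated once per gene (multi-assignment); per gene, body and regulatory
#' are mutually exclusive.
#'
#' @param positions tibble with `chrom`, `pos` (unique positions; extra
#'   columns carried through).
#' @param genes gene-model tibble (see [generate_annotation()] /
#'   [read_gene_models()]).
#' @return tibble: input columns plus `region` and `gene` (`NA` for
#'   intergenic); one row per (position, gene) pair.
#' @export
assign_region <- function(positions, genes) {
  pos_tbl <- distinct(positions, .data$chrom, .data$pos, .keep_all = TRUE)
  chrom_len <- attr(genes, "chrom_length")
  if (!is.null(chrom_len) && any(pos_tbl$pos > chrom_len | pos_tbl$pos < 1)) {
    abort("position(s) beyond chromosome bounds")
  }
  q <- IRanges::IRanges(start = pos_tbl$pos, width = 1L)

  body <- IRanges::IRanges(start = genes$start, end = genes$end)
  fwd <- genes$strand != "-"
  reg_start <- ifelse(fwd, genes$start - 5500L, genes$end + 1L)
  reg_end <- ifelse(fwd, genes$start - 1L, genes$end + 5500L)
  if (all(c("reg_start", "reg_end") %in% names(genes))) {
    reg_start <- genes$reg_start
    reg_end <- genes$reg_end
  }
  reg <- IRanges::IRanges(start = pmax(reg_start, 1L), end = reg_end)

  hit_b <- IRanges::findOverlaps(q, body)
  hit_r <- IRanges::findOverlaps(q, reg)
  res <- bind_rows(
    tibble(
      row = S4Vectors::queryHits(hit_b), region = "body",
      gene = genes$gene[S4Vectors::subjectHits(hit_b)]
    ),
    tibble(
      row = S4Vectors::queryHits(hit_r), region = "regulatory",
      gene = genes$gene[S4Vectors::subjectHits(hit_r)]
    )
  )
  inter <- setdiff(seq_len(nrow(pos_tbl)), unique(res$row))
  res <- bind_rows(
    res,
    tibble(row = inter, region = "intergenic", gene = NA_character_)
  )
  out <- bind_cols(pos_tbl[res$row, , drop = FALSE],
                   select(res, "region", "gene"))
  arrange(out, .data$pos, .data$region)
}

#' Per-gene methylation levels by region
#'
#' For each gene and region (`body`, `regulatory`), the methylation level is
#' the number of differentially methylated cytosines divided by all evaluated
#' cytosines in that region. Genes with zero evaluated cytosines in a region
#' carry `NA` (undefined) and are excluded from downstream distribution
#' tests.
#'
#' @param calls DMC table from [dm_test()] (evaluated cytosines only).
#' @param assignments region assignment table from [assign_region()] covering
#'   the evaluated cytosines.
#' @return tibble: `gene`, `region`, `n_evaluated`, `n_dmc`, `level`.
#' @export
methylation_level <- function(calls, assignments) {
  d <- inner_join(
    select(calls, "chrom", "pos", "is_dmc"),
    select(assignments, "chrom", "pos", "region", "gene"),
    by = c("chrom", "pos")
  ) %>%
    filter(!is.na(.data$gene), .data$region %in% c("body", "regulatory"))
  d %>%
    group_by(.data$gene, .data$region) %>%
    summarise(
      n_evaluated = n(), n_dmc = sum(.data$is_dmc),
      .groups = "drop"
    ) %>%
    mutate(level = .data$n_dmc / .data$n_evaluated)
}
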