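# Linking DNA methylation to network topology: preserved-vs-unpreserved
# methylation-level distributions and regressions of methylation level on
# gene network properties.

#' Differential coexpression score
#'
#' For gene `g`, the score is `1 - pearson(c_A(g), c_B(g))` where `c_X(g)` is
#' the vector of `g`'s correlations to all other shared genes in condition
#' `X`. The score lies in `[0, 2]`: 0 means identical coexpression pattern,
#' values near 1 arise when the two patterns are unrelated, larger values
#' indicate inversion. (The score's exact form is an implementation choice;
#' see the methods vignette.)
#'
#' @param expr_a,expr_b `normalized_expr` objects or tibbles with a `gene`
#'   column; gene sets are intersected.
#' @return tibble: `gene`, `dc_score`.
#' @export
differential_coexpression_score <- function(expr_a, expr_b) {
  ma <- values_matrix(expr_a, "expr_a")
  mb <- values_matrix(expr_b, "expr_b")
  shared <- intersect(rownames(ma), rownames(mb))
  if (length(shared) < 3) abort("need at least 3 shared genes")
  ca <- row_cor(ma[shared, , drop = FALSE])
  cb <- row_cor(mb[shared, , drop = FALSE])
  n <- length(shared)
  score <- vapply(seq_len(n), function(g) {
    va <- ca[g, -g]
    vb <- cb[g, -g]
    if (sd(va) == 0 || sd(vb) == 0) return(NA_real_)
    1 - cor(va, vb)
  }, numeric(1))
  tibble(gene = shared, dc_score = score)
}

#' Assemble per-gene network properties with preservation classes
#'
#' Joins module assignment, own-module membership (kME), intramodular
#' connectivity (kIM), differential coexpression score, the module's
#' preservation class, and an optional transcription-factor flag into the
#' per-gene property table used by the integration analyses.
#'
#' @param network a `coex_network` from [build_network()].
#' @param preservation a `module_preservation` from [module_preservation()].
#' @param dc_scores tibble from [differential_coexpression_score()].
#' @param tf_genes optional character vector of transcription-factor gene
#'   ids.
#' @return tibble: `gene`, `module`, `class`, `kme`, `kim`, `dc_score`,
#'   `is_tf`. Background (grey) genes carry `NA` class and kME.
#' @export
gene_network_properties <- function(network, preservation, dc_scores,
                                    tf_genes = character()) {
  mods <- network$modules
  own_kme <- vapply(seq_len(nrow(mods)), function(i) {
    mod <- mods$module[i]
    if (mod == "grey" || is.null(network$kme) ||
        !mod %in% names(network$kme)) {
      return(NA_real_)
    }
    network$kme[[mod]][network$kme$gene == mods$gene[i]]
  }, numeric(1))
  out <- mods %>%
    mutate(kme = own_kme, is_tf = .data$gene %in% tf_genes) %>%
    left_join(select(network$kim, "gene", "kim"), by = "gene") %>%
    left_join(dc_scores, by = "gene") %>%
    left_join(select(preservation$summary, "module", "class"), by = "module")
  out$class[out$module == "grey"] <- NA_character_
  select(out, "gene", "module", "class", "kme", "kim", "dc_score", "is_tf")
}

# preserved = weak_moderate or strong; unpreserved per classification
preservation_stratum <- function(class) {
  ifelse(is.na(class), NA_character_,
         ifelse(class == "unpreserved", "unpreserved", "preserved"))
}

#' Compare methylation-level distributions between preserved and unpreserved
#' modules
#'
#' Two-sample two-sided Kolmogorov-Smirnov test between the methylation
#' levels of genes in unpreserved modules and genes in preserved modules
#' (weak-to-moderate and strong classes pooled), for one region. Genes with
#' undefined level in the region are excluded.
#'
#' @param levels per-gene methylation levels from [methylation_level()].
#' @param props per-gene properties from [gene_network_properties()].
#' @param region `"body"` or `"regulatory"`.
#' @param tf_only restrict to transcription factors.
#' @return tibble: `region`, `tf_only`, `n_preserved`, `n_unpreserved`,
#'   `ks_statistic`, `p_value`.
#' @export
compare_level_distributions <- function(levels, props,
                                        region = c("body", "regulatory"),
                                        tf_only = FALSE) {
  region <- match.arg(region)
  d <- integration_table(levels, props, region)
  if (tf_only) d <- d[d$is_tf, , drop = FALSE]
  x <- d$level[d$stratum == "unpreserved"]
  y <- d$level[d$stratum == "preserved"]
  if (!length(x)) abort("unpreserved stratum is empty")
  if (!length(y)) abort("preserved stratum is empty")
  kt <- suppressWarnings(ks.test(x, y, alternative = "two.sided"))
  tibble(
    region = region, tf_only = tf_only,
    n_preserved = length(y), n_unpreserved = length(x),
    ks_statistic = unname(kt$statistic), p_value = kt$p.value
  )
}

#' Regress methylation level on a gene network property
#'
#' Ordinary least squares of methylation level (response) on one network
#' property (predictor), within one preservation stratum and region.
#'
#' @inheritParams compare_level_distributions
#' @param property `"kim"`, `"kme"`, or `"dc_score"`.
#' @param stratum `"preserved"` or `"unpreserved"`.
#' @return tibble: `property`, `region`, `stratum`, `n`, `beta`, `se`,
#'   `p_value`.
#' @export
regress_level_on_property <- function(levels, props,
                                      property = c("kim", "kme", "dc_score"),
                                      region = c("body", "regulatory"),
                                      stratum = c("preserved", "unpreserved")) {
  property <- match.arg(property)
  region <- match.arg(region)
  stratum <- match.arg(stratum)
  d <- integration_table(levels, props, region)
  d <- d[d$stratum == stratum & !is.na(d[[property]]), , drop = FALSE]
  if (nrow(d) < 3) abort("fewer than 3 genes with defined level and property")
  x <- d[[property]]
  if (sd(x) == 0) abort("constant predictor")
  fit <- lm(d$level ~ x)
  cf <- summary(fit)$coefficients
  tibble(
    property = property, region = region, stratum = stratum, n = nrow(d),
    beta = cf[2, 1], se = cf[2, 2], p_value = cf[2, 4]
  )
}

# join levels (one region) with properties; keep genes in scored modules
integration_table <- function(levels, props, region) {
  lv <- levels[levels$region == region & !is.na(levels$level), , drop = FALSE]
  d <- inner_join(lv, props, by = "gene")
  d$stratum <- preservation_stratum(d$class)
  d[!is.na(d$stratum), , drop = FALSE]
}

#' Integration summary: all KS comparisons and regressions
#'
#' Runs [compare_level_distributions()] for both regions (all genes, and the
#' TF subset when present) and [regress_level_on_property()] for every
#' property x region x stratum combination with enough data.
#'
#' @inheritParams compare_level_distributions
#' @return list with `ks` and `regressions` tibbles.
#' @export
integration_summary <- function(levels, props) {
  ks <- list()
  for (region in c("body", "regulatory")) {
    for (tf_only in if (any(props$is_tf)) c(FALSE, TRUE) else FALSE) {
      r <- tryCatch(
        compare_level_distributions(levels, props, region, tf_only = tf_only),
        error = function(e) NULL
      )
      if (!is.null(r)) ks[[length(ks) + 1L]] <- r
    }
  }
  regs <- list()
  for (property in c("kim", "kme", "dc_score")) {
    for (region in c("body", "regulatory")) {
      for (stratum in c("preserved", "unpreserved")) {
        r <- tryCatch(
          regress_level_on_property(levels, props, property, region, stratum),
          error = function(e) NULL
        )
        if (!is.null(r)) regs[[length(regs) + 1L]] <- r
      }
    }
  }
  list(ks = list_rbind(ks), regressions = list_rbind(regs))
}
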