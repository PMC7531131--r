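# CpG filtering, differential-methylation testing, region assignment,
# per-gene methylation levels.

# long cytosine tibble from per-site specs: list(pos, context, cov (matrix
# samples), meth (matrix samples))
cyt_table <- function(pos, cov_a, meth_a, cov_b, meth_b, context = "CpG") {
  na <- length(cov_a); nb <- length(cov_b)
  tibble::tibble(
    chrom = "chrS", pos = pos, strand = "+", context = context,
    sample = c(sprintf("a%d", seq_len(na)), sprintf("b%d", seq_len(nb))),
    group = c(rep("A", na), rep("B", nb)),
    count_methylated = c(meth_a, meth_b),
    count_unmethylated = c(cov_a - meth_a, cov_b - meth_b)
  )
}

test_that("coverage and context filters follow the >= 8 CpG rule", {
  d <- dplyr::bind_rows(
    cyt_table(1, rep(7, 4), rep(3, 4), rep(7, 4), rep(3, 4)),     # all cov 7
    cyt_table(2, rep(8, 4), rep(4, 4), rep(8, 4), rep(4, 4)),     # boundary 8
    cyt_table(3, rep(100, 4), rep(50, 4), rep(100, 4), rep(50, 4),
              context = "CHH"),                                    # wrong context
    cyt_table(4, c(30, 30, 5, 5), c(10, 10, 2, 2),
              c(30, 30, 30, 30), rep(10, 4))                       # 2 A-samples left
  )
  out <- filter_cytosines(d, min_coverage = 8, min_samples_per_group = 3)
  expect_equal(sort(unique(out$pos)), 2L)  # only the boundary site survives
  out2 <- filter_cytosines(d, min_coverage = 8, min_samples_per_group = 2)
  expect_setequal(unique(out2$pos), c(2L, 4L))
  # low-coverage records within a retained cytosine are dropped
  expect_equal(sum(out2$pos == 4 & out2$group == "A"), 2)
})

test_that("the closed-form LRT equals binomial logistic regression via glm", {
  set.seed(1)
  rows <- list()
  for (i in 1:40) {
    cov_a <- rpois(5, 25) + 8; cov_b <- rpois(6, 25) + 8
    pa <- runif(1, 0.05, 0.95); pb <- runif(1, 0.05, 0.95)
    rows[[i]] <- cyt_table(i, cov_a, rbinom(5, cov_a, pa),
                           cov_b, rbinom(6, cov_b, pb))
  }
  d <- dplyr::bind_rows(rows)
  calls <- dm_test(d)
  for (i in sample(40, 10)) {
    di <- d[d$pos == i, ]
    fit <- glm(cbind(count_methylated, count_unmethylated) ~ group,
               family = binomial, data = di)
    fit0 <- glm(cbind(count_methylated, count_unmethylated) ~ 1,
                family = binomial, data = di)
    p_ref <- anova(fit0, fit, test = "Chisq")$`Pr(>Chi)`[2]
    if (is.na(p_ref)) p_ref <- 1  # identical-deviance corner
    expect_equal(calls$p_value[calls$pos == i], p_ref, tolerance = 1e-8)
  }
})

test_that("the DMC rule needs both a > 20% change and q <= 0.10", {
  # identical groups: delta 0, never a DMC
  d1 <- cyt_table(1, rep(50, 5), rep(20, 5), rep(50, 5), rep(20, 5))
  c1 <- dm_test(d1)
  expect_equal(c1$delta_percent, 0)
  expect_false(c1$is_dmc)

  # massive counts, 15% change: q tiny but effect below the threshold
  d2 <- cyt_table(1, rep(5000, 5), rep(2000, 5), rep(5000, 5), rep(2750, 5))
  c2 <- dm_test(d2)
  expect_lt(c2$q_value, 1e-6)
  expect_equal(c2$delta_percent, 15)
  expect_false(c2$is_dmc)

  # 25% change with strong evidence: a DMC
  d3 <- cyt_table(1, rep(500, 5), rep(200, 5), rep(500, 5), rep(325, 5))
  c3 <- dm_test(d3)
  expect_true(c3$is_dmc)

  # complete separation is flagged
  d4 <- cyt_table(1, rep(20, 5), rep(0, 5), rep(20, 5), rep(20, 5))
  c4 <- dm_test(d4)
  expect_true(c4$separation)
  expect_true(is.finite(c4$p_value))
})

test_that("null data yield DMC calls at no more than the q threshold", {
  set.seed(5)
  fracs <- sapply(1:3, function(s) {
    cfg <- sim_config(
      n_genes = 40, module_sizes = c(15L, 15L),
      body_dmc_rate = 0, reg_dmc_rate = 0, intergenic_dmc_rate = 0,
      n_samples_meth_a = 6, n_samples_meth_b = 6,
      body_cpg_per_gene = 8, reg_cpg_per_gene = 4, n_intergenic_cpg = 50,
      seed = s
    )
    sim <- simulate_study(cfg)
    calls <- dm_test(filter_cytosines(sim$cytosines))
    mean(calls$is_dmc)
  })
  expect_lte(mean(fracs), 0.10)
})

test_that("positions map to body, regulatory and intergenic regions", {
  cfg <- sim_config(n_genes = 20, module_sizes = 10L, seed = 2)
  ann <- generate_annotation(cfg)
  g1 <- ann[1, ]
  iv <- gene_model_intervals(ann)
  exon1 <- iv[iv$gene == g1$gene & iv$feature == "exon", ][1, ]
  pos <- tibble::tibble(
    chrom = "chrS",
    pos = c(exon1$start,            # inside an exon -> body
            g1$start - 1000L,       # 1 kb upstream -> regulatory
            g1$start - 5500L,       # far edge of the window -> regulatory
            g1$start - 5501L,       # just beyond the window
            g1$end + 2000L)         # inside the downstream gap
  )
  out <- assign_region(pos, ann)
  get <- function(p) out[out$pos == p, ]
  expect_equal(get(exon1$start)$region, "body")
  expect_equal(get(exon1$start)$gene, g1$gene)
  expect_equal(get(g1$start - 1000L)$region, "regulatory")
  expect_equal(get(g1$start - 5500L)$region, "regulatory")
  expect_equal(get(g1$start - 5501L)$region, "intergenic")
  expect_equal(get(g1$end + 2000L)$region, "intergenic")
  expect_error(
    assign_region(tibble::tibble(chrom = "chrS", pos = 10^9), ann),
    "bounds"
  )
})

test_that("per gene, body and regulatory assignments are disjoint and
          exhaustive", {
  cfg <- sim_config(n_genes = 30, module_sizes = 10L, seed = 3,
                    body_cpg_per_gene = 6, reg_cpg_per_gene = 3)
  sim <- simulate_study(cfg)
  pos <- dplyr::distinct(sim$cytosines, chrom, pos)
  out <- assign_region(pos, sim$genes)
  expect_setequal(unique(out$region), c("body", "regulatory", "intergenic"))
  # every queried position received at least one label
  expect_setequal(unique(out$pos), unique(pos$pos))
  dup <- out |>
    dplyr::filter(!is.na(gene)) |>
    dplyr::count(pos, gene) |>
    dplyr::filter(n > 1)
  expect_equal(nrow(dup), 0)
  # assignments agree with the generator's own ground truth
  joined <- dplyr::inner_join(
    out, sim$cytosine_truth, by = c("chrom", "pos"),
    suffix = c("", "_truth")
  )
  expect_true(all(joined$region == joined$region_truth))
})

test_that("methylation levels are DMC counts over evaluated counts", {
  calls <- tibble::tibble(
    chrom = "chrS", pos = 1:12, strand = "+",
    is_dmc = c(rep(FALSE, 8), rep(TRUE, 2), FALSE, TRUE)
  )
  asn <- tibble::tibble(
    chrom = "chrS", pos = 1:12,
    region = c(rep("body", 10), "regulatory", "regulatory"),
    gene = "gX"
  )
  lv <- methylation_level(calls, asn)
  body <- lv[lv$region == "body", ]
  expect_equal(body$n_evaluated, 10)
  expect_equal(body$n_dmc, 2)
  expect_equal(body$level, 0.2)
  reg <- lv[lv$region == "regulatory", ]
  expect_equal(reg$level, 0.5)
})

test_that("pipeline levels equal a brute-force recount", {
  cfg <- sim_config(n_genes = 40, module_sizes = c(15L, 15L), seed = 7,
                    body_dmc_rate = 0.2, reg_dmc_rate = 0.2)
  sim <- simulate_study(cfg)
  calls <- dm_test(filter_cytosines(sim$cytosines))
  asn <- assign_region(dplyr::distinct(calls, chrom, pos), sim$genes)
  lv <- methylation_level(calls, asn)
  expect_true(all(lv$level >= 0 & lv$level <= 1))
  expect_true(all(lv$n_dmc <= lv$n_evaluated))
  # recount for a handful of genes directly from the joined tables
  joined <- dplyr::inner_join(calls, asn, by = c("chrom", "pos"))
  for (g in head(unique(lv$gene), 5)) {
    for (r in c("body", "regulatory")) {
      sub <- joined[!is.na(joined$gene) & joined$gene == g &
                      joined$region == r, ]
      if (!nrow(sub)) next
      row <- lv[lv$gene == g & lv$region == r, ]
      expect_equal(row$n_evaluated, nrow(sub))
      expect_equal(row$n_dmc, sum(sub$is_dmc))
    }
  }
})
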