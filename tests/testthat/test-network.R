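# Adjacency, TOM, soft-threshold scan, dynamic tree cut, eigengenes,
# merging, membership, connectivity.

test_that("adjacency equals |cor|^power, with exact special cases", {
  x <- c(1, 2, 3, 4, 5, 6)
  m <- rbind(a = x, b = 2 * x + 3, c = -x + 10)  # perfectly correlated set
  colnames(m) <- paste0("s", 1:6)
  a <- adjacency(expr_from_matrix(m), power = 7)
  expect_equal(unname(a[1, 2]), 1)
  expect_equal(unname(a[1, 3]), 1)  # |−1|^power = 1

  set.seed(4)
  m2 <- matrix(rnorm(20 * 10), 20, 10)
  rownames(m2) <- sprintf("g%03d", 1:20)
  a2 <- adjacency(expr_from_matrix(m2), power = 6)
  # brute-force double loop
  for (i in 1:20) {
    for (j in 1:20) {
      expected <- if (i == j) 1 else abs(cor(m2[i, ], m2[j, ]))^6
      expect_equal(unname(a2[i, j]), expected, tolerance = 1e-12)
    }
  }
})

test_that("zero-variance genes are rejected by name", {
  m <- rbind(g1 = c(1, 2, 3, 4), flat = c(2, 2, 2, 2))
  expect_error(adjacency(expr_from_matrix(m), 6), "flat")
})

test_that("TOM matches hand values and a triple-loop oracle", {
  # 3 genes, all off-diagonal adjacency 0.5:
  # tom_12 = (l + a) / (min(k) + 1 - a) = (0.25 + 0.5) / (1 + 0.5) = 0.5
  a <- matrix(0.5, 3, 3); diag(a) <- 1
  tm <- tom_similarity(a)
  expect_equal(tm$tom[1, 2], 0.5)
  expect_equal(diag(tm$tom), rep(1, 3))
  expect_equal(tm$diss, 1 - tm$tom)

  # no connections -> all off-diagonal TOM 0
  tm0 <- tom_similarity(diag(3))
  expect_equal(tm0$tom[lower.tri(tm0$tom)], rep(0, 3))

  # random symmetric adjacency vs O(n^3) reference
  set.seed(5)
  n <- 15
  a <- matrix(runif(n * n, 0, 0.9), n, n)
  a <- (a + t(a)) / 2; diag(a) <- 1
  tm <- tom_similarity(a)
  ref <- matrix(1, n, n)
  for (i in 1:n) {
    for (j in 1:n) {
      if (i == j) next
      l <- 0
      for (u in 1:n) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
      ref[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
    }
  }
  expect_equal(tm$tom, ref, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("soft-threshold scan handles degenerate and vacuous inputs", {
  # all genes scaled copies of one profile: every |cor| = 1, all k equal
  z <- rnorm(8)
  m <- outer(seq(1, 3, length.out = 12), z)
  rownames(m) <- sprintf("g%03d", 1:12)
  expect_warning(
    ps <- pick_soft_threshold(expr_from_matrix(m), powers = c(2, 4, 6)),
    "no candidate power"
  )
  expect_true(ps$warning)
  expect_true(all(ps$scan$fit_r2 == 0))

  # r2_cut = 0: any fit qualifies, so the smallest candidate power is chosen
  set.seed(6)
  m2 <- matrix(rnorm(60 * 12), 60, 12)
  rownames(m2) <- sprintf("g%03d", 1:60)
  ps2 <- pick_soft_threshold(expr_from_matrix(m2), powers = c(3, 5, 9),
                             r2_cut = 0)
  expect_equal(ps2$power, 3)
})

test_that("scan connectivity is non-increasing in power and R2 matches an
          independent regression", {
  sim <- planted_expr(2, n_samples = 16, n_modules = 3, module_size = 30,
                      n_background = 60)
  na <- normalize_counts(sim$expr_a)
  ps <- suppressWarnings(pick_soft_threshold(na, powers = c(2, 4, 6, 8)))
  expect_true(all(diff(ps$scan$mean_k) < 0))

  # recompute the fit index for power 4 from scratch
  m <- as.matrix(na$log_cpm[, -1])
  k <- colSums(abs(cor(t(m)))^4) - 1
  bin <- cut(k, 10, include.lowest = TRUE)
  dk <- tapply(k, bin, mean); pk <- tapply(k, bin, length) / length(k)
  keep <- !is.na(dk) & dk > 0 & pk > 0
  fit <- lm(log10(pk[keep]) ~ log10(dk[keep]))
  expected <- -sign(coef(fit)[2]) * summary(fit)$r.squared
  expect_equal(ps$scan$fit_r2[ps$scan$power == 4], unname(expected),
               tolerance = 1e-12)
})

test_that("tree cut recovers perfectly separated blocks and rejects
          structureless input", {
  d <- matrix(1, 20, 20)
  d[1:10, 1:10] <- 0; d[11:20, 11:20] <- 0; diag(d) <- 0
  rownames(d) <- colnames(d) <- sprintf("g%02d", 1:20)
  out <- cluster_and_cut(d, min_module_size = 3)
  lab <- out$modules$module
  expect_equal(length(unique(lab)), 2)
  expect_equal(length(unique(lab[1:10])), 1)
  expect_equal(length(unique(lab[11:20])), 1)
  expect_false(any(lab == "grey"))

  # all-equal dissimilarities: no branch structure, everything background
  d2 <- matrix(0.7, 25, 25); diag(d2) <- 0
  rownames(d2) <- colnames(d2) <- sprintf("g%02d", 1:25)
  out2 <- cluster_and_cut(d2, min_module_size = 3)
  expect_true(all(out2$modules$module == "grey"))

  # fewer genes than the minimum size: single background module
  d3 <- matrix(0.5, 4, 4); diag(d3) <- 0
  rownames(d3) <- colnames(d3) <- paste0("g", 1:4)
  out3 <- cluster_and_cut(d3, min_module_size = 10)
  expect_true(all(out3$modules$module == "grey"))
})

test_that("planted modules are recovered from TOM dissimilarity (ARI >= 0.8)", {
  for (seed in 1:3) {
    sim <- planted_expr(seed, n_samples = 40)
    na <- normalize_counts(sim$expr_a)
    net <- build_network(na, power = 8)
    ari <- rand_index_adj(sim$truth$genes$module, net$modules$module)
    expect_gte(ari, 0.8)
  }
})

test_that("module eigengenes: rank-1 block, sign convention, variance share", {
  # identical profiles: varExplained = 1, eigengene = standardized profile
  z <- rnorm(10)
  m <- rbind(a = z, b = z, c = z, d = 2 * z + 5)
  colnames(m) <- paste0("s", 1:10)
  mods <- tibble::tibble(gene = c("a", "b", "c", "d"), module = "M1")
  me <- module_eigengenes(expr_from_matrix(m), mods)
  expect_equal(me$var_explained$var_explained, 1)
  v <- me$eigengenes$M1
  zs <- (z - mean(z)) / sd(z)
  expect_equal(v / sqrt(sum(v^2)), zs / sqrt(sum(zs^2)), tolerance = 1e-10)
  expect_gt(cor(v, zs), 0)  # sign aligned with the mean profile

  # random module: varExplained equals the leading share of the gene-gene
  # correlation spectrum (independent eigen-decomposition)
  set.seed(9)
  m2 <- matrix(rnorm(8 * 12), 8, 12)
  rownames(m2) <- paste0("g", 1:8); colnames(m2) <- paste0("s", 1:12)
  mods2 <- tibble::tibble(gene = rownames(m2), module = "M1")
  me2 <- module_eigengenes(expr_from_matrix(m2), mods2)
  lambda <- eigen(cor(t(m2)), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(me2$var_explained$var_explained, lambda[1] / sum(lambda),
               tolerance = 1e-10)
})

test_that("eigengene is invariant to gene order and errors on constant genes", {
  set.seed(10)
  m <- matrix(rnorm(6 * 9), 6, 9)
  rownames(m) <- paste0("g", 1:6); colnames(m) <- paste0("s", 1:9)
  mods <- tibble::tibble(gene = rownames(m), module = "M1")
  me1 <- module_eigengenes(expr_from_matrix(m), mods)
  perm <- c(4, 2, 6, 1, 3, 5)
  me2 <- module_eigengenes(expr_from_matrix(m[perm, ]), mods[perm, ])
  expect_equal(me1$eigengenes$M1, me2$eigengenes$M1, tolerance = 1e-10)

  m_bad <- rbind(m, flat = rep(1, 9))
  mods_bad <- tibble::tibble(gene = rownames(m_bad), module = "M1")
  expect_error(module_eigengenes(expr_from_matrix(m_bad), mods_bad),
               "constant")
})

test_that("modules with identical eigengenes merge; orthogonal ones do not", {
  set.seed(11)
  z1 <- rnorm(30); z2 <- rnorm(30)
  noise <- function(n) matrix(rnorm(n * 30, sd = 0.05), n)
  m <- rbind(
    t(outer(z1, runif(5, 0.8, 1.2))) + noise(5),   # module 1: factor z1
    t(outer(z1, runif(5, 0.8, 1.2))) + noise(5),   # module 2: same factor
    t(outer(z2, runif(5, 0.8, 1.2))) + noise(5)    # module 3: independent
  )
  rownames(m) <- sprintf("g%02d", 1:15); colnames(m) <- sprintf("s%02d", 1:30)
  mods <- tibble::tibble(
    gene = rownames(m), module = rep(c("M1", "M2", "M3"), each = 5)
  )
  expr <- expr_from_matrix(m)
  merged <- merge_modules(expr, mods, cor_cut = 0.8)
  expect_equal(length(unique(merged$module)), 2)  # M1+M2 fused, M3 separate
  expect_equal(length(unique(merged$module[1:10])), 1)
  expect_false(merged$module[11] == merged$module[1])
  # idempotence
  expect_identical(merge_modules(expr, merged, cor_cut = 0.8), merged)
})

test_that("chained eigengene correlations follow the single-linkage rule", {
  # factors with cor(z1,z2) ~ 0.85, cor(z2,z3) ~ 0.85, cor(z1,z3) ~ 0.5:
  # single linkage at height 0.2 chains all three into one module
  set.seed(12)
  n <- 400
  z2 <- rnorm(n)
  z1 <- 0.85 * z2 + sqrt(1 - 0.85^2) * rnorm(n)
  z3 <- 0.85 * z2 + sqrt(1 - 0.85^2) * rnorm(n)
  build <- function(z) t(outer(z, rep(1, 6))) + matrix(rnorm(6 * n, sd = 0.01), 6)
  m <- rbind(build(z1), build(z2), build(z3))
  rownames(m) <- sprintf("g%02d", 1:18); colnames(m) <- sprintf("s%03d", 1:n)
  mods <- tibble::tibble(gene = rownames(m),
                         module = rep(c("M1", "M2", "M3"), each = 6))
  expr <- expr_from_matrix(m)
  # independent prediction from the realized eigengene correlations
  e <- module_eigengenes(expr, mods)$eigengenes
  emat <- as.matrix(e[, -1])
  hc <- hclust(as.dist(1 - cor(emat)), method = "single")
  expected_groups <- max(cutree(hc, h = 0.2))
  merged <- merge_modules(expr, mods, cor_cut = 0.8)
  expect_equal(length(unique(merged$module)), expected_groups)
  expect_equal(expected_groups, 1)  # chain case collapses fully
})

test_that("signed kME equals brute-force gene-eigengene correlation", {
  sim <- planted_expr(3, n_samples = 15, n_modules = 2, module_size = 20,
                      n_background = 20)
  na <- normalize_counts(sim$expr_a)
  mods <- truth_modules(sim$truth$genes)
  me <- module_eigengenes(na, mods)
  kme <- signed_kme(na, me$eigengenes)
  m <- as.matrix(na$log_cpm[, -1])
  rownames(m) <- na$log_cpm$gene
  for (g in c(1, 10, 41)) {
    for (mod in c("M1", "M2")) {
      expect_equal(kme[[mod]][g],
                   cor(m[g, ], me$eigengenes[[mod]]), tolerance = 1e-12)
    }
  }
  # a gene identical to its eigengene has kME 1
  m2 <- rbind(m[1:20, ], ME = me$eigengenes$M1)
  kme2 <- signed_kme(expr_from_matrix(m2), me$eigengenes)
  expect_equal(kme2$M1[21], 1)
})

test_that("intramodular connectivity equals masked row sums", {
  # module of m genes with all adjacencies 1: kIM = m - 1
  a <- matrix(1, 4, 4)
  rownames(a) <- colnames(a) <- paste0("g", 1:4)
  mods <- tibble::tibble(gene = rownames(a), module = "M1")
  kim <- intramodular_connectivity(a, mods)
  expect_equal(kim$kim, rep(3, 4))

  # singleton module: kIM = 0
  mods2 <- tibble::tibble(gene = rownames(a), module = c("M1", "M1", "M1", "M2"))
  kim2 <- intramodular_connectivity(a, mods2)
  expect_equal(kim2$kim[4], 0)

  # random case vs brute-force loop
  set.seed(13)
  n <- 12
  a3 <- matrix(runif(n * n), n, n); a3 <- (a3 + t(a3)) / 2; diag(a3) <- 1
  rownames(a3) <- colnames(a3) <- sprintf("g%02d", 1:n)
  lab <- sample(c("M1", "M2", "grey"), n, replace = TRUE)
  mods3 <- tibble::tibble(gene = rownames(a3), module = lab)
  kim3 <- intramodular_connectivity(a3, mods3)
  for (i in 1:n) {
    expected <- 0
    for (j in 1:n) {
      if (j != i && lab[j] == lab[i]) expected <- expected + a3[i, j]
    }
    expect_equal(kim3$kim[i], expected, tolerance = 1e-12)
  }
})

test_that("tidy and glance summarize a fitted network", {
  sim <- planted_expr(4, n_samples = 30, n_modules = 2, module_size = 20,
                      n_background = 20)
  na <- normalize_counts(sim$expr_a)
  net <- build_network(na, power = 8, min_module_size = 15)
  td <- tidy(net)
  expect_named(td, c("gene", "module", "kme", "kim"))
  expect_equal(nrow(td), 60)
  gl <- glance(net)
  expect_equal(gl$n_genes, 60)
  expect_true(gl$n_modules >= 1)
})
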