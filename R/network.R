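#' Choose the soft-thresholding power by scale-free topology fit
#'
#' For each candidate power, computes whole-network connectivity
#' `k_i = sum_j |cor_ij|^power` and the scale-free fit index: `log10 p(k)` is
#' regressed on `log10 k` over equal-count bins of `k`, and the fit index is
#' the regression R-squared, negated when the slope is positive (a scale-free
#' network requires frequency to decay with connectivity). Returns the
#' smallest power whose fit reaches `r2_cut`.
#'
#' @param expr a `normalized_expr` or tibble with a `gene` column
#'   (genes x samples, log2-CPM scale).
#' @param powers candidate powers.
#' @param r2_cut minimum acceptable fit index (default 0.8).
#' @param n_bins number of equal-count connectivity bins.
#' @return list with `power` (chosen), `scan` (tibble: `power`, `fit_r2`,
#'   `slope`, `mean_k`, `median_k`, `max_k`) and `warning` (`TRUE` when no
#'   power reached `r2_cut`, or the connectivity histogram was degenerate).
#' @export
pick_soft_threshold <- function(expr, powers = 1:20, r2_cut = 0.8,
                                n_bins = 10) {
  if (length(powers) < 2) abort("supply at least 2 candidate powers")
  m <- values_matrix(expr)
  if (ncol(m) < 4) abort("need at least 4 samples")
  acor <- abs(row_cor(m))
  scan <- map(powers, function(p) {
    k <- colSums(acor^p) - 1  # exclude self
    fit <- scale_free_fit(k, n_bins)
    tibble(
      power = p, fit_r2 = fit$r2, slope = fit$slope,
      mean_k = mean(k), median_k = median(k), max_k = max(k),
      degenerate = fit$degenerate
    )
  })
  scan <- list_rbind(scan)
  if (r2_cut <= 0) {
    # vacuous criterion: every candidate qualifies
    return(list(power = min(powers), scan = select(scan, -"degenerate"),
                warning = any(scan$degenerate)))
  }
  ok <- which(scan$fit_r2 >= r2_cut)
  warning_flag <- any(scan$degenerate)
  if (length(ok)) {
    power <- scan$power[ok[1]]
  } else {
    power <- scan$power[which.max(scan$fit_r2)]
    warning_flag <- TRUE
    warn(sprintf(
      "no candidate power reached fit R^2 >= %.2f; returning power %g (max fit %.3f)",
      r2_cut, power, max(scan$fit_r2)
    ))
  }
  list(power = power, scan = select(scan, -"degenerate"),
       warning = warning_flag)
}

# Scale-free fit of a connectivity vector: log10 p(k) ~ log10 k over
# equal-width bins of k. Degenerate histograms (a single usable bin) give
# r2 = 0.
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < 2 || diff(range(k)) < .Machine$double.eps^0.5) {
    return(list(r2 = 0, slope = NA_real_, degenerate = TRUE))
  }
  bin <- cut(k, n_bins, include.lowest = TRUE)
  dk <- tapply(k, bin, mean)
  pk <- tapply(k, bin, length) / length(k)
  keep <- !is.na(dk) & dk > 0 & pk > 0
  if (sum(keep) < 3) {
    return(list(r2 = 0, slope = NA_real_, degenerate = TRUE))
  }
  x <- log10(dk[keep]); y <- log10(pk[keep])
  fit <- lm(y ~ x)
  slope <- unname(coef(fit)[2])
  r2 <- summary(fit)$r.squared
  list(r2 = -sign(slope) * r2, slope = slope, degenerate = FALSE)
}

#' Unsigned soft-thresholded adjacency
#'
#' `a_ij = |pearson(x_i, x_j)|^power`, with unit diagonal.
#'
#' @inheritParams pick_soft_threshold
#' @param power soft-thresholding power (beta).
#' @return symmetric numeric matrix with gene dimnames and attribute `power`.
#' @export
adjacency <- function(expr, power) {
  if (power <= 0) abort("power must be positive")
  m <- values_matrix(expr)
  a <- abs(row_cor(m))^power
  diag(a) <- 1
  attr(a, "power") <- power
  a
}

#' Topological overlap matrix
#'
#' For genes i != j:
#' `tom_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_{u != i,j} a_iu a_uj` (shared-neighbour strength) and
#' `k_i = sum_{u != i} a_iu` (connectivity); `tom_ii = 1`. The returned
#' dissimilarity `diss = 1 - tom` is the clustering distance.
#'
#' @param adj adjacency matrix from [adjacency()].
#' @return list with `tom` and `diss` matrices.
#' @export
tom_similarity <- function(adj) {
  a <- unclass(adj)
  stopifnot(is.matrix(a), nrow(a) == ncol(a))
  a2 <- a %*% a
  l <- a2 - 2 * a          # removes u = i and u = j terms (diag(a) = 1)
  k <- rowSums(a) - 1
  min_k <- outer(k, k, pmin)
  tom <- (l + a) / (min_k + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  list(tom = tom, diss = 1 - tom)
}

# ---------------------------------------------------------------------------
# Dynamic hybrid tree cut
#
# Shape-and-height branch decomposition of an average-linkage dendrogram:
#  * the dendrogram is traversed bottom-up in merge order below a cut height
#    (0.99 of the 5th-percentile..max height range);
#  * a growing branch is "locked" as a module when, at the moment it merges
#    with another qualifying branch (or is attached above the cut height), it
#    has >= min_module_size members, a low core scatter (mean of its lowest
#    merge heights below a deep_split-dependent threshold) and a sufficient
#    gap between its core and the merge height;
#  * members whose mean within-module dissimilarity exceeds the core-scatter
#    threshold are stripped, then all unassigned genes are PAM-style
#    reassigned to the nearest module, gated at the same threshold.
# deep_split (0..4) maps to a core-scatter quantile of the height range:
# 0.64, 0.73, 0.82, 0.91, 0.95; the minimum gap is 3/4 of its complement.
# ---------------------------------------------------------------------------

#' Detect modules by dynamic hybrid cutting of a dendrogram
#'
#' Average-linkage hierarchical clustering on a TOM dissimilarity followed by
#' a hybrid shape-and-height branch cut with PAM-like reassignment of
#' outlying leaves. Genes not assigned to any module are labelled `"grey"`
#' (background); modules are labelled `"M1"`, `"M2"`, ... in decreasing size
#' order.
#'
#' @param diss symmetric dissimilarity matrix (`1 - TOM`), or the list
#'   returned by [tom_similarity()].
#' @param min_module_size smallest cluster retained as a module.
#' @param deep_split integer 0-4; larger values split more aggressively.
#' @param cut_height maximum joining height considered, or `NULL` for 99% of
#'   the (5th percentile, maximum) height range.
#' @return list with `modules` (tibble: `gene`, `module`) and `hclust` (the
#'   dendrogram).
#' @export
cluster_and_cut <- function(diss, min_module_size = 30, deep_split = 2,
                            cut_height = NULL) {
  if (is.list(diss) && !is.data.frame(diss)) diss <- diss$diss
  stopifnot(is.matrix(diss), nrow(diss) == ncol(diss))
  genes <- rownames(diss) %||% sprintf("g%d", seq_len(nrow(diss)))
  n <- nrow(diss)
  if (n < min_module_size) {
    return(list(
      modules = tibble(gene = genes, module = "grey"),
      hclust = NULL
    ))
  }
  hc <- hclust(as.dist(diss), method = "average")
  lab_int <- cutree_hybrid(hc, diss, min_module_size, deep_split, cut_height)
  list(modules = tibble(gene = genes, module = label_modules(lab_int)),
       hclust = hc)
}

# integer labels (0 = background) -> "grey"/"M1".. by decreasing size
label_modules <- function(lab) {
  out <- rep("grey", length(lab))
  if (any(lab > 0)) {
    sizes <- sort(table(lab[lab > 0]), decreasing = TRUE)
    new <- setNames(sprintf("M%d", seq_along(sizes)), names(sizes))
    out[lab > 0] <- new[as.character(lab[lab > 0])]
  }
  out
}

cutree_hybrid <- function(hc, diss, min_module_size = 30, deep_split = 2,
                          cut_height = NULL) {
  n <- length(hc$order)
  h <- hc$height
  base <- unname(quantile(h, 0.05))
  top <- max(h)
  if (top - base < .Machine$double.eps^0.5) return(rep(0L, n))
  cut_h <- cut_height %||% (base + 0.99 * (top - base))
  max_core_scatter <- c(0.64, 0.73, 0.82, 0.91, 0.95)[deep_split + 1]
  core_abs <- base + max_core_scatter * (cut_h - base)
  gap_abs <- (1 - max_core_scatter) * 3 / 4 * (cut_h - base)

  # one bottom-up pass: members, merge heights and core height per node
  members <- vector("list", n - 1)
  heights <- vector("list", n - 1)
  core <- rep(NA_real_, n - 1)
  n_core <- max(min_module_size - 1, 1)
  for (t in seq_len(n - 1)) {
    get_m <- function(id) if (id < 0) -id else members[[id]]
    get_h <- function(id) if (id < 0) numeric(0) else heights[[id]]
    members[[t]] <- c(get_m(hc$merge[t, 1]), get_m(hc$merge[t, 2]))
    heights[[t]] <- c(get_h(hc$merge[t, 1]), get_h(hc$merge[t, 2]), h[t])
    hs <- sort(heights[[t]])
    core[t] <- mean(hs[seq_len(min(length(hs), n_core))])
  }
  node_size <- function(id) if (id < 0) 1L else length(members[[id]])
  node_core <- function(id) if (id < 0) NA_real_ else core[id]
  # a child branch is "distinct" at merge height ht when it is large enough,
  # compact, and separated from its sibling by a clear gap
  distinct <- function(id, ht) {
    if (node_size(id) < min_module_size) return(FALSE)
    ch <- node_core(id)
    !is.na(ch) && ch <= core_abs && (ht - ch) >= gap_abs
  }

  # top-down decomposition (explicit stack: no recursion-depth limit)
  clusters <- list()
  pool <- integer()
  stack <- n - 1L
  while (length(stack)) {
    id <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (id < 0 || node_size(id) < min_module_size) {
      pool <- c(pool, if (id < 0) -id else members[[id]])
      next
    }
    c1 <- hc$merge[id, 1]
    c2 <- hc$merge[id, 2]
    ht <- h[id]
    if (ht > cut_h || distinct(c1, ht) || distinct(c2, ht)) {
      stack <- c(stack, c1, c2)
    } else if (core[id] <= core_abs) {
      clusters[[length(clusters) + 1L]] <- members[[id]]
    } else {
      # incompact node: descend into sizeable children, pool the rest
      for (ch in c(c1, c2)) {
        if (node_size(ch) >= min_module_size) {
          stack <- c(stack, ch)
        } else {
          pool <- c(pool, if (ch < 0) -ch else members[[ch]])
        }
      }
    }
  }
  if (!length(clusters)) return(rep(0L, n))

  lab <- rep(0L, n)
  for (i in seq_along(clusters)) lab[clusters[[i]]] <- i

  # strip outlying members: mean within-module dissimilarity far above the
  # module's own distribution (self-calibrating; TOM dissimilarities can sit
  # anywhere in [0, 1] depending on network size and power)
  for (i in seq_along(clusters)) {
    mem <- which(lab == i)
    if (length(mem) < 3) next
    d_in <- rowSums(diss[mem, mem, drop = FALSE]) / (length(mem) - 1)
    thr <- median(d_in) + 3 * stats::mad(d_in)
    lab[mem[d_in > thr]] <- 0L
  }
  # dissolve modules that fell below size
  for (i in seq_along(clusters)) {
    if (sum(lab == i) < min_module_size) lab[lab == i] <- 0L
  }

  # PAM-like reassignment of unlabelled genes: join the closest module when
  # the gene is no farther than that module's 90th-percentile internal
  # dissimilarity
  mods <- sort(unique(lab[lab > 0]))
  if (length(mods)) {
    unass <- which(lab == 0L)
    if (length(unass)) {
      gate <- numeric(length(mods))
      d_to <- matrix(0, length(unass), length(mods))
      for (j in seq_along(mods)) {
        mem <- which(lab == mods[j])
        d_in <- rowSums(diss[mem, mem, drop = FALSE]) / (length(mem) - 1)
        # midpoint between the module's internal dissimilarity level and the
        # typical gene-to-module distance: a gene joins only when it is
        # closer to the module's core than to the bulk of the network
        gate[j] <- (median(d_in) + median(rowMeans(diss[, mem]))) / 2
        d_to[, j] <- rowMeans(diss[unass, mem, drop = FALSE])
      }
      best <- max.col(-d_to, ties.method = "first")
      best_d <- d_to[cbind(seq_along(unass), best)]
      take <- best_d <= gate[best]
      lab[unass[take]] <- mods[best[take]]
    }
  }
  lab
}

#' Module eigengenes and explained variance
#'
#' The eigengene of a module is the first right-singular vector of its
#' standardized gene x sample expression block (equivalently the first
#' principal component of the module expression data), sign-aligned to
#' correlate positively with the module's average standardized expression.
#' The proportion of variance explained is the first squared singular value
#' over the total.
#'
#' @inheritParams pick_soft_threshold
#' @param modules tibble with columns `gene`, `module` (`"grey"` =
#'   background, excluded).
#' @return list with `eigengenes` (tibble: `sample` + one unit-norm column
#'   per module) and `var_explained` (tibble: `module`, `var_explained`).
#' @export
module_eigengenes <- function(expr, modules) {
  m <- values_matrix(expr)
  mods <- setdiff(sort(unique(modules$module)), "grey")
  if (!length(mods)) abort("no non-background modules")
  me <- matrix(NA_real_, ncol(m), length(mods),
               dimnames = list(colnames(m), mods))
  ve <- numeric(length(mods))
  for (j in seq_along(mods)) {
    genes <- modules$gene[modules$module == mods[j]]
    if (length(genes) < 2) abort(sprintf("module %s has fewer than 2 genes", mods[j]))
    block <- m[genes, , drop = FALSE]
    sds <- apply(block, 1, sd)
    if (any(sds == 0)) {
      abort(sprintf("module %s contains constant gene(s)", mods[j]))
    }
    xs <- (block - rowMeans(block)) / sds
    sv <- svd(xs)
    v1 <- sv$v[, 1]
    if (cor(v1, colMeans(xs)) < 0) v1 <- -v1
    me[, j] <- v1
    ve[j] <- sv$d[1]^2 / sum(sv$d^2)
  }
  list(
    eigengenes = bind_cols(tibble(sample = colnames(m)),
                           as_tibble(me, .name_repair = "minimal")),
    var_explained = tibble(module = mods, var_explained = ve)
  )
}

eigengene_matrix <- function(eigengenes) {
  e <- as.matrix(eigengenes[setdiff(names(eigengenes), "sample")])
  rownames(e) <- eigengenes$sample
  e
}

#' Merge modules with highly correlated eigengenes
#'
#' Iteratively: compute eigengenes, single-linkage cluster them on the
#' correlation dissimilarity `1 - cor`, merge every group joined below
#' `1 - cor_cut`, recompute, and repeat until no pair of eigengenes
#' correlates at `cor_cut` or above. Background genes are untouched.
#'
#' @inheritParams module_eigengenes
#' @param cor_cut minimum eigengene Pearson correlation for merging.
#' @return tibble `gene`, `module` with merged labels (`"M1"`... by size).
#' @export
merge_modules <- function(expr, modules, cor_cut = 0.8) {
  repeat {
    mods <- setdiff(unique(modules$module), "grey")
    if (length(mods) < 2) break
    e <- eigengene_matrix(module_eigengenes(expr, modules)$eigengenes)
    d <- 1 - cor(e)
    hc <- hclust(as.dist(d), method = "single")
    grp <- cutree(hc, h = 1 - cor_cut)
    if (max(grp) == length(grp)) break  # nothing joined
    remap <- setNames(sprintf("tmp%d", grp), names(grp))
    modules$module[modules$module != "grey"] <-
      remap[modules$module[modules$module != "grey"]]
  }
  lab <- modules$module
  out <- rep(0L, length(lab))
  mods <- setdiff(unique(lab), "grey")
  out[lab != "grey"] <- match(lab[lab != "grey"], mods)
  tibble(gene = modules$gene, module = label_modules(out))
}

#' Signed module membership (kME)
#'
#' `kME_{g,m} = pearson(expression_g, eigengene_m)`, signed.
#'
#' @inheritParams pick_soft_threshold
#' @param eigengenes eigengene tibble from [module_eigengenes()].
#' @return tibble: `gene` + one kME column per module.
#' @export
signed_kme <- function(expr, eigengenes) {
  m <- values_matrix(expr)
  e <- eigengene_matrix(eigengenes)
  k <- cor(t(m), e)
  bind_cols(tibble(gene = rownames(m)),
            as_tibble(k, .name_repair = "minimal"))
}

#' Intramodular connectivity (kIM)
#'
#' Sum of a gene's adjacencies to the other genes of its own module;
#' background genes are scored over the background set.
#'
#' @param adj adjacency matrix from [adjacency()].
#' @param modules tibble `gene`, `module`.
#' @return tibble: `gene`, `module`, `kim`.
#' @export
intramodular_connectivity <- function(adj, modules) {
  a <- unclass(adj)
  stopifnot(all(modules$gene %in% rownames(a)))
  kim <- numeric(nrow(modules))
  for (mod in unique(modules$module)) {
    genes <- modules$gene[modules$module == mod]
    idx <- match(genes, rownames(a))
    block <- a[idx, idx, drop = FALSE]
    kim[modules$module == mod] <- rowSums(block) - diag(block)
  }
  tibble(gene = modules$gene, module = modules$module, kim = kim)
}

#' Build the reference coexpression network
#'
#' Full condition-A workflow: soft-threshold selection (unless `power` is
#' given), unsigned adjacency, TOM, average-linkage clustering with the
#' dynamic hybrid cut, eigengenes, merging of correlated modules
#' (eigengene correlation >= `merge_cor`), and per-gene kME and kIM.
#'
#' @inheritParams pick_soft_threshold
#' @inheritParams cluster_and_cut
#' @param power soft threshold; `NULL` to select via [pick_soft_threshold()].
#' @param merge_cor eigengene correlation at or above which modules merge.
#' @param keep_adjacency retain the adjacency matrix in the result (memory
#'   scales with genes squared).
#' @return object of class `coex_network`: list with `modules`, `eigengenes`,
#'   `var_explained`, `kme`, `kim`, `power`, `scan`, `hclust`, and optionally
#'   `adjacency`.
#' @export
build_network <- function(expr, powers = 1:20, r2_cut = 0.8, power = NULL,
                          min_module_size = 30, deep_split = 2,
                          merge_cor = 0.8, keep_adjacency = FALSE) {
  scan <- NULL
  if (is.null(power)) {
    ps <- pick_soft_threshold(expr, powers, r2_cut)
    power <- ps$power
    scan <- ps$scan
  }
  adj <- adjacency(expr, power)
  tom <- tom_similarity(adj)
  cut <- cluster_and_cut(tom$diss, min_module_size, deep_split)
  modules <- cut$modules
  if (any(modules$module != "grey")) {
    modules <- merge_modules(expr, modules, merge_cor)
    me <- module_eigengenes(expr, modules)
    kme <- signed_kme(expr, me$eigengenes)
  } else {
    me <- list(eigengenes = NULL, var_explained = NULL)
    kme <- NULL
  }
  kim <- intramodular_connectivity(adj, modules)
  out <- list(
    modules = modules, eigengenes = me$eigengenes,
    var_explained = me$var_explained, kme = kme, kim = kim,
    power = power, scan = scan, hclust = cut$hclust
  )
  if (keep_adjacency) out$adjacency <- adj
  structure(out, class = "coex_network")
}

#' @export
print.coex_network <- function(x, ...) {
  sizes <- table(x$modules$module)
  n_mod <- sum(names(sizes) != "grey")
  cat(sprintf(
    "Coexpression network: %d genes, power %g, %d modules (+ %d background genes)\n",
    nrow(x$modules), x$power, n_mod,
    if ("grey" %in% names(sizes)) sizes[["grey"]] else 0L
  ))
  if (n_mod) {
    s <- sizes[names(sizes) != "grey"]
    cat("module sizes:", paste(sprintf("%s=%d", names(s), s), collapse = ", "), "\n")
  }
  invisible(x)
}
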