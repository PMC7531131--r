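#' Simulation configuration for the two-condition coexpression/methylation study
#'
#' Bundles every knob of the synthetic-data generator: a two-condition
#' expression design with planted coexpression modules (a chosen subset of
#' which is destroyed or attenuated in condition B), matching gene models on a
#' single synthetic chromosome, and CpG-level methylation counts with planted
#' group-differential cytosines.
#'
#' Defaults mirror a maternal-diet muscle study design: 9 vs 10 expression
#' replicates and 7 vs 9 methylation replicates.
#'
#' @param n_genes total number of genes (module genes + background).
#' @param module_sizes integer vector of planted module sizes; background genes
#'   make up `n_genes - sum(module_sizes)`.
#' @param n_samples_a,n_samples_b expression replicates per condition.
#' @param perturbed_modules integer indices of modules whose coexpression
#'   structure is removed (or attenuated) in condition B.
#' @param within_module_cor target pairwise Pearson correlation of the latent
#'   profiles of genes in the same module, in (0, 1].
#' @param loading_spread half-width of the per-gene jitter applied to
#'   `within_module_cor`, giving genes heterogeneous loadings (and hence a
#'   within-module connectivity gradient). Set to 0 for exchangeable genes.
#' @param perturb_mode `"destroy"` replaces perturbed modules by independent
#'   noise in condition B; `"attenuate"` multiplies their loadings by
#'   `attenuation`.
#' @param attenuation loading multiplier for `perturb_mode = "attenuate"`.
#' @param latent_amplitude standard deviation of the latent log-expression
#'   signal (natural-log scale).
#' @param nb_dispersion negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`).
#' @param library_size_range min/max sequencing depth per sample (reads).
#' @param base_log_mean,base_log_sd mean/sd of per-gene baseline natural-log
#'   relative expression.
#' @param n_samples_meth_a,n_samples_meth_b methylation replicates per group.
#' @param meth_delta planted group difference in methylation proportion at
#'   differentially methylated cytosines (DMCs).
#' @param coverage_range min/max read coverage per cytosine per sample.
#' @param low_coverage_frac fraction of cytosine/sample records forced below
#'   coverage 8, to exercise the coverage filter.
#' @param body_dmc_rate baseline probability that a gene-body CpG is a planted
#'   DMC.
#' @param reg_dmc_rate same for regulatory-region CpGs.
#' @param intergenic_dmc_rate same for intergenic CpGs.
#' @param perturbed_body_enrichment multiplier on `body_dmc_rate` for genes in
#'   perturbed modules (plants the body-methylation/preservation contrast).
#' @param meth_kim_coupling nonnegative coupling between a preserved-module
#'   gene's loading (standardized within module) and its body DMC rate:
#'   rate is multiplied by `exp(-coupling * z_loading)`, so better-connected
#'   genes receive fewer DMCs (plants a negative methylation-connectivity
#'   slope in preserved modules only).
#' @param body_cpg_per_gene,reg_cpg_per_gene expected CpG count per gene body /
#'   regulatory window.
#' @param n_intergenic_cpg number of intergenic CpGs.
#' @param frac_non_cpg fraction of additional non-CpG-context cytosines added
#'   to exercise the context filter.
#' @param seed integer seed; the same configuration and seed reproduce every
#'   output bit-identically.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 600,
                       module_sizes = rep(50L, 6L),
                       n_samples_a = 9L,
                       n_samples_b = 10L,
                       perturbed_modules = integer(),
                       within_module_cor = 0.7,
                       loading_spread = 0.12,
                       perturb_mode = c("destroy", "attenuate"),
                       attenuation = 0.3,
                       latent_amplitude = 1.2,
                       nb_dispersion = 0.02,
                       library_size_range = c(8e5, 1.2e6),
                       base_log_mean = log(150),
                       base_log_sd = 1,
                       n_samples_meth_a = 7L,
                       n_samples_meth_b = 9L,
                       meth_delta = 0.4,
                       coverage_range = c(10L, 50L),
                       low_coverage_frac = 0.05,
                       body_dmc_rate = 0.05,
                       reg_dmc_rate = 0.05,
                       intergenic_dmc_rate = 0.05,
                       perturbed_body_enrichment = 6,
                       meth_kim_coupling = 0,
                       body_cpg_per_gene = 20,
                       reg_cpg_per_gene = 8,
                       n_intergenic_cpg = 200L,
                       frac_non_cpg = 0.05,
                       seed = 1L) {
  perturb_mode <- match.arg(perturb_mode)
  module_sizes <- as.integer(module_sizes)
  n_modules <- length(module_sizes)
  if (any(module_sizes < 2L)) abort("module sizes must be >= 2")
  if (sum(module_sizes) > n_genes) {
    abort("sum(module_sizes) exceeds n_genes: no room for background genes")
  }
  if (length(perturbed_modules) &&
      !all(perturbed_modules %in% seq_len(n_modules))) {
    abort("perturbed_modules must be a subset of module indices")
  }
  if (within_module_cor <= 0 || within_module_cor > 1) {
    abort("within_module_cor must be in (0, 1]")
  }
  if (n_samples_a < 3L || n_samples_b < 3L) abort("need >= 3 samples per condition")
  cfg <- list(
    n_genes = as.integer(n_genes), module_sizes = module_sizes,
    n_modules = n_modules,
    n_background = as.integer(n_genes) - sum(module_sizes),
    n_samples_a = as.integer(n_samples_a), n_samples_b = as.integer(n_samples_b),
    perturbed_modules = as.integer(perturbed_modules),
    within_module_cor = within_module_cor, loading_spread = loading_spread,
    perturb_mode = perturb_mode, attenuation = attenuation,
    latent_amplitude = latent_amplitude, nb_dispersion = nb_dispersion,
    library_size_range = library_size_range,
    base_log_mean = base_log_mean, base_log_sd = base_log_sd,
    n_samples_meth_a = as.integer(n_samples_meth_a),
    n_samples_meth_b = as.integer(n_samples_meth_b),
    meth_delta = meth_delta, coverage_range = as.integer(coverage_range),
    low_coverage_frac = low_coverage_frac,
    body_dmc_rate = body_dmc_rate, reg_dmc_rate = reg_dmc_rate,
    intergenic_dmc_rate = intergenic_dmc_rate,
    perturbed_body_enrichment = perturbed_body_enrichment,
    meth_kim_coupling = meth_kim_coupling,
    body_cpg_per_gene = body_cpg_per_gene, reg_cpg_per_gene = reg_cpg_per_gene,
    n_intergenic_cpg = as.integer(n_intergenic_cpg),
    frac_non_cpg = frac_non_cpg,
    seed = as.integer(seed)
  )
  structure(cfg, class = "sim_config")
}

gene_ids <- function(n) sprintf("g%04d", seq_len(n))

# Per-gene squared loadings (target correlations), jittered around
# within_module_cor and clipped to (0.02, 1].
sim_loadings <- function(config) {
  n_mod_genes <- sum(config$module_sizes)
  rho <- config$within_module_cor +
    config$loading_spread * runif(n_mod_genes, -1, 1)
  pmin(pmax(rho, 0.02), 1)
}

#' Generate two-condition expression count matrices with planted modules
#'
#' Condition A contains every planted module as a latent-factor block: each
#' module gene's latent profile is `sqrt(rho_g) * z_m + sqrt(1 - rho_g) * eps`,
#' where `z_m` is the module's latent factor across samples, so any two module
#' genes correlate at `sqrt(rho_g * rho_h)` (about `within_module_cor`).
#' Latent profiles are mapped through an exponential mean function to
#' negative-binomial counts at the sample's library size. Condition B redraws
#' factors and noise: non-perturbed modules keep their loadings (structure
#' preserved), perturbed modules are replaced by independent noise (or
#' attenuated), and background genes are independent everywhere.
#'
#' @param config a [sim_config()].
#' @return list with `expr_a`, `expr_b` (tibbles: `gene` + sample columns of
#'   counts), and `truth` (list with `genes` and `modules` tibbles; module
#'   label 0 denotes background).
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  ids <- gene_ids(n)
  labels <- rep(0L, n)
  idx <- 1L
  for (m in seq_len(config$n_modules)) {
    labels[idx:(idx + config$module_sizes[m] - 1L)] <- m
    idx <- idx + config$module_sizes[m]
  }
  rho <- rep(NA_real_, n)
  rho[labels > 0L] <- sim_loadings(config)

  base_log <- rnorm(n, config$base_log_mean, config$base_log_sd)

  latent_for <- function(n_samples, keep_structure) {
    z <- matrix(rnorm(config$n_modules * n_samples), config$n_modules)
    y <- matrix(rnorm(n * n_samples), n)  # iid noise / background profiles
    # standardize profiles across samples so the planted correlation is
    # realized at the target value rather than attenuated or inflated by
    # finite-sample variance fluctuations of the shared factor
    z <- (z - rowMeans(z)) / apply(z, 1, sd)
    y <- (y - rowMeans(y)) / apply(y, 1, sd)
    for (g in which(labels > 0L)) {
      m <- labels[g]
      a2 <- rho[g] * keep_structure[m]
      y[g, ] <- sqrt(a2) * z[m, ] + sqrt(1 - a2) * y[g, ]
    }
    y
  }

  counts_from_latent <- function(y) {
    n_samples <- ncol(y)
    lib <- runif(n_samples, config$library_size_range[1], config$library_size_range[2])
    p <- exp(base_log)
    p <- p / sum(p)
    mu <- (p * exp(config$latent_amplitude * y)) %*% diag(lib, n_samples)
    cnt <- matrix(
      rnbinom(length(mu), mu = as.vector(mu), size = 1 / config$nb_dispersion),
      nrow = n
    )
    rownames(cnt) <- ids
    cnt
  }

  keep_a <- rep(1, config$n_modules)
  keep_b <- rep(1, config$n_modules)
  keep_b[config$perturbed_modules] <-
    if (config$perturb_mode == "destroy") 0 else config$attenuation^2

  y_a <- latent_for(config$n_samples_a, keep_a)
  cnt_a <- counts_from_latent(y_a)
  colnames(cnt_a) <- sprintf("A%02d", seq_len(config$n_samples_a))
  y_b <- latent_for(config$n_samples_b, keep_b)
  cnt_b <- counts_from_latent(y_b)
  colnames(cnt_b) <- sprintf("B%02d", seq_len(config$n_samples_b))

  truth <- list(
    genes = tibble(gene = ids, module = labels, loading_cor = rho),
    modules = tibble(
      module = seq_len(config$n_modules),
      size = config$module_sizes,
      perturbed = seq_len(config$n_modules) %in% config$perturbed_modules
    )
  )
  list(expr_a = expr_tibble(cnt_a), expr_b = expr_tibble(cnt_b), truth = truth)
}

#' Generate non-overlapping gene models on one synthetic chromosome
#'
#' Lays out `n_genes` forward-strand gene models left to right with intergenic
#' gaps, each with 1-4 exons separated by introns and a 5.5-kb regulatory
#' window immediately upstream of the transcription start site. Coordinates
#' are 1-based inclusive.
#'
#' @param config a [sim_config()].
#' @return tibble with columns `gene`, `chrom`, `strand`, `start`, `end`,
#'   `exon_starts`, `exon_ends` (comma-separated), `reg_start`, `reg_end`;
#'   attribute `chrom_length`.
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- config$n_genes
  ids <- gene_ids(n)
  reg_width <- 5500L
  gap <- 4000L
  lens <- sample(2000:8000, n, replace = TRUE)
  n_ex <- sample(1:4, n, replace = TRUE)

  pos <- reg_width + gap + 1L  # leave room for the first regulatory window
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    start <- pos
    end <- start + lens[i] - 1L
    # cut the gene span into alternating exons/introns: 2*k-1 pieces
    k <- n_ex[i]
    n_pieces <- 2L * k - 1L
    cuts <- sort(sample(seq_len(lens[i] - 1L), n_pieces - 1L))
    bounds <- c(0L, cuts, lens[i])
    piece_start <- start + bounds[-length(bounds)]
    piece_end <- start + bounds[-1] - 1L
    exon_i <- seq(1L, n_pieces, by = 2L)
    rows[[i]] <- tibble(
      gene = ids[i], chrom = "chrS", strand = "+",
      start = start, end = end,
      exon_starts = paste(piece_start[exon_i], collapse = ","),
      exon_ends = paste(piece_end[exon_i], collapse = ","),
      reg_start = start - reg_width, reg_end = start - 1L
    )
    pos <- end + gap + reg_width + 1L
  }
  out <- list_rbind(rows)
  attr(out, "chrom_length") <- max(out$end) + gap
  out
}

#' Generate CpG-level methylation counts with planted differential cytosines
#'
#' Places CpGs in gene bodies, regulatory windows, and intergenic gaps, then
#' draws per-sample binomial methylated/unmethylated counts. A planted DMC
#' shifts the group-B methylation proportion by `meth_delta` (direction chosen
#' to stay inside (0, 1)). DMC placement probability is elevated in gene
#' bodies of perturbed-module genes and, when `meth_kim_coupling > 0`,
#' decreases with a preserved-module gene's loading. A fraction of records is
#' forced below coverage 8 and a fraction of sites carries non-CpG context, so
#' downstream filters are exercised.
#'
#' @param config a [sim_config()].
#' @param genes gene models from [generate_annotation()].
#' @param truth the `truth` element of [generate_expression()].
#' @return list with `cytosines` (long tibble: `chrom`, `pos`, `strand`,
#'   `context`, `sample`, `group`, `count_methylated`, `count_unmethylated`)
#'   and `cytosine_truth` (tibble: `chrom`, `pos`, `region`, `gene`, `is_dmc`,
#'   `p_a`, `p_b`).
#' @export
generate_methylation <- function(config, genes, truth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)

  tg <- truth$genes
  perturbed_set <- truth$modules$module[truth$modules$perturbed]
  # standardized loading within each preserved module (for the kIM coupling)
  zload <- rep(0, nrow(tg))
  for (m in setdiff(unique(tg$module), c(0L, perturbed_set))) {
    sel <- tg$module == m
    lc <- tg$loading_cor[sel]
    s <- sd(lc)
    zload[sel] <- if (is.na(s) || s == 0) 0 else (lc - mean(lc)) / s
  }

  body_rate <- ifelse(
    tg$module %in% perturbed_set,
    pmin(config$body_dmc_rate * config$perturbed_body_enrichment, 0.9),
    pmin(config$body_dmc_rate * exp(-config$meth_kim_coupling * zload), 0.9)
  )
  # background genes: baseline, no coupling
  body_rate[tg$module == 0L] <- config$body_dmc_rate

  sites <- vector("list", nrow(genes) * 2L + 1L)
  si <- 1L
  for (i in seq_len(nrow(genes))) {
    nb <- max(3L, rpois(1, config$body_cpg_per_gene))
    nr <- max(1L, rpois(1, config$reg_cpg_per_gene))
    span_b <- genes$start[i]:genes$end[i]
    span_r <- genes$reg_start[i]:genes$reg_end[i]
    pb <- sort(sample(span_b, min(nb, length(span_b))))
    pr <- sort(sample(span_r, min(nr, length(span_r))))
    sites[[si]] <- tibble(
      pos = pb, region = "body", gene = genes$gene[i],
      dmc_rate = body_rate[match(genes$gene[i], tg$gene)]
    )
    sites[[si + 1L]] <- tibble(
      pos = pr, region = "regulatory", gene = genes$gene[i],
      dmc_rate = config$reg_dmc_rate
    )
    si <- si + 2L
  }
  # intergenic gaps: between a gene end and the next regulatory window
  gaps_lo <- c(1L, genes$end[-nrow(genes)] + 1L)
  gaps_hi <- c(genes$reg_start - 1L)
  gap_pool <- unlist(map2(gaps_lo, gaps_hi, function(a, b) if (b > a + 1L) (a + 1L):(b - 1L) else integer()))
  pi_ <- sort(sample(gap_pool, min(config$n_intergenic_cpg, length(gap_pool))))
  sites[[si]] <- tibble(
    pos = pi_, region = "intergenic", gene = NA_character_,
    dmc_rate = config$intergenic_dmc_rate
  )
  site_tbl <- list_rbind(sites)
  site_tbl <- site_tbl[!duplicated(site_tbl$pos), ]

  n_sites <- nrow(site_tbl)
  is_dmc <- runif(n_sites) < site_tbl$dmc_rate
  p0 <- runif(n_sites, 0.1, 0.9)
  dir <- ifelse(p0 <= 0.5, 1, -1)
  p_a <- p0
  p_b <- ifelse(is_dmc, pmin(pmax(p0 + dir * config$meth_delta, 0.01), 0.99), p0)

  context <- rep("CpG", n_sites)
  n_non <- round(config$frac_non_cpg * n_sites)
  if (n_non > 0) {
    non_idx <- sample(n_sites, n_non)
    context[non_idx] <- sample(c("CHG", "CHH"), n_non, replace = TRUE)
    is_dmc[non_idx] <- FALSE  # non-CpG sites are never planted DMCs
  }

  samples <- c(
    sprintf("mA%02d", seq_len(config$n_samples_meth_a)),
    sprintf("mB%02d", seq_len(config$n_samples_meth_b))
  )
  groups <- c(
    rep("A", config$n_samples_meth_a),
    rep("B", config$n_samples_meth_b)
  )

  per_sample <- vector("list", length(samples))
  for (s in seq_along(samples)) {
    p <- if (groups[s] == "A") p_a else p_b
    cov <- round(runif(n_sites, config$coverage_range[1], config$coverage_range[2]))
    low <- runif(n_sites) < config$low_coverage_frac
    cov[low] <- sample(0:7, sum(low), replace = TRUE)
    meth <- rbinom(n_sites, cov, p)
    per_sample[[s]] <- tibble(
      chrom = "chrS", pos = site_tbl$pos, strand = "+", context = context,
      sample = samples[s], group = groups[s],
      count_methylated = meth, count_unmethylated = cov - meth
    )
  }

  list(
    cytosines = list_rbind(per_sample),
    cytosine_truth = tibble(
      chrom = "chrS", pos = site_tbl$pos, region = site_tbl$region,
      gene = site_tbl$gene, context = context,
      is_dmc = is_dmc, p_a = p_a, p_b = p_b
    )
  )
}

#' Run the full synthetic study generator
#'
#' Convenience wrapper producing expression (both conditions), annotation and
#' methylation from one configuration.
#'
#' @param config a [sim_config()].
#' @return list with `expr_a`, `expr_b`, `truth`, `genes`, `cytosines`,
#'   `cytosine_truth`.
#' @export
simulate_study <- function(config) {
  ex <- generate_expression(config)
  ann <- generate_annotation(config)
  me <- generate_methylation(config, ann, ex$truth)
  c(ex, list(genes = ann), me)
}
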