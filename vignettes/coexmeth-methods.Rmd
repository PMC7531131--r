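---
title: "Models and methods behind coexmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind coexmeth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`coexmeth` tests whether an experimental condition rewires gene coexpression
and whether DNA methylation tracks that rewiring. This vignette documents
the models, the tunable parameters, the numerical choices, and what the
synthetic validation does and does not establish.

## 1. The coexpression model

Expression is analyzed on the log2-CPM scale after TMM normalization. The
reference network is *unsigned* and *weighted*:

- adjacency `a_ij = |cor(x_i, x_j)|^beta`. The soft threshold `beta`
  emphasizes strong correlations without a hard cutoff. It is chosen as the
  smallest candidate for which the connectivity distribution is approximately
  scale-free: `log10 p(k)` regressed on `log10 k` over ten equal-width bins
  of `k`, fit index = R² with the sign of the slope folded in (a fit with a
  positive slope — frequency *increasing* with connectivity — is counted as
  negative evidence). Equal-width bins are used deliberately: equal-count
  bins would make the frequency histogram flat by construction and the
  regression meaningless.
- the topological overlap matrix
  `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 − a_ij)`,
  `l_ij = Σ_{u≠i,j} a_iu a_uj`, `k_i = Σ_{u≠i} a_iu`, rewards shared
  neighbourhoods and is the basis of the clustering distance `1 − TOM`.
  For an isolated pair with `a_ij = 1` the same formula applies (denominator
  1, TOM 1).

**Caveat for small designs.** The scale-free criterion is informative for
transcriptome-scale networks; small planted-module designs (hundreds of
genes) are modular rather than scale-free, and the scan then tends toward
extreme powers that crush the signal. For such designs the package's
validation runs fix `beta = 8`, the standard recommendation for unsigned
networks at 20–30 samples; `pick_soft_threshold()` remains the tool for
real data.

## 2. Dynamic hybrid tree cut

The reference tree-cut algorithm is not reproducible in detail from its
usual descriptions, so `cluster_and_cut()` implements its own
shape-and-height hybrid, which is validated against planted ground truth:

1. Average-linkage clustering of `1 − TOM`.
2. Heights are calibrated by `base` (5th percentile of joining heights) and
   `cut_height` (99% of the base-to-maximum range). `deep_split` (0–4, default
   2) maps to a *core-scatter* quantile {0.64, 0.73, 0.82, 0.91, 0.95} of
   that range; the minimum branch *gap* is 3/4 of its complement.
3. Top-down decomposition: a node splits when it merges above `cut_height`
   or when either child is *distinct* (at least `min_module_size` leaves,
   core scatter — the mean of its lowest merge heights — below the
   threshold, and a sufficient gap between its core and the merge height).
   A node that cannot be split and is compact becomes a module; incompact
   nodes are descended into sizeable children, and leftovers are pooled as
   background.
4. Cleanup is self-calibrating, because TOM dissimilarities can compress
   anywhere in [0, 1] depending on network size and power: members whose
   mean within-module dissimilarity exceeds the module median + 3 MAD are
   stripped; pooled genes are PAM-style reassigned to the closest module if
   they are nearer the module's internal median dissimilarity than the
   typical gene-to-module distance (midpoint rule).

Degenerate inputs behave sensibly: all-equal dissimilarities give no
modules; perfectly separated blocks are recovered exactly; fewer genes than
`min_module_size` give a single background module.

Module eigengenes are first right-singular vectors of the standardized
gene × sample block, sign-aligned to correlate positively with the module's
mean standardized profile; the explained-variance share equals the leading
eigenvalue share of the gene-gene correlation spectrum. Modules whose
eigengenes correlate at ≥ 0.8 are merged by single linkage at height 0.2
(so correlation chains merge transitively), iterating until stable.
Iterative re-merging was chosen over a single pass so the output is a fixed
point of the merge operator (idempotence is tested).

## 3. Module preservation

Twelve statistics are computed per reference module, all higher-is-better:

- *density* (is the module still densely connected in the test data?):
  `meanSignAwareCorDat`, `meanAdj`, `propVarExplained`, `meanSignAwareKME`,
  `meanClusterCoeff`, `meanMAR`;
- *connectivity* (is the internal topology preserved?): correlations between
  reference and test values of kIM, kME, pairwise correlations, adjacency,
  clustering coefficient and maximum adjacency ratio within the module.

The exact panel used in the motivating analysis is not published in full;
this 6 + 6 panel is the canonical one for the composite construction below.

The permutation null reassigns module labels *in the test data only*:
the reference side of every statistic is always the true module, the test
side a random same-size gene set (paired by position). This choice is
load-bearing — a null that permutes both sides jointly collapses (zero
permutation SD for all connectivity statistics) when the test data equal
the reference data, whereas the implemented null yields the expected
strong self-preservation. Defaults: 2000 permutations for full runs
(validation uses 200–500); a statistic with zero null SD is flagged
(`Z = Inf`) and excluded from the composite medians.

Composites: `Z_density` and `Z_connectivity` are medians of the
per-statistic `Z = (obs − null mean)/null SD`; `Z_summary` is their mean;
`medianRank` is the mean of the density and connectivity median ranks of
the observed statistics across modules (rank 1 = most preserved; ties
averaged). Classification: *unpreserved* iff `Z_summary ≤ 2` **and**
`medianRank > n_modules/2` (strict inequality at exactly half);
*strong* iff `Z_summary > 10`; otherwise *weak-to-moderate*.

## 4. Preprocessing choices

- Low-count rule: a gene is removed when its count is ≤ 5 in at least 9
  replicates, applied jointly across all samples; the abundant-gene list is
  an explicit input (muscle data are dominated by a few dozen contractile
  genes).
- TMM: trim fractions 0.30 (M-values) and 0.05 (A-values) per tail,
  inverse-variance weighting, reference sample = the one whose
  upper-quartile expression is closest to the mean upper quartile, factors
  rescaled to geometric mean 1. These constants match the canonical
  formulation, verified against an independent implementation to 1e-6 in
  the tests. Exact invariance to rescaling one library holds for the
  trimmed mean itself; the precision weights depend weakly on absolute
  counts, so the invariance is near-exact (tested at 0.02).
- Variance filter: top `⌈0.5 n⌉` genes by log2-CPM variance (prior count
  0.5 avoids log 0); the scale on which variance is taken is unstated in
  the field's descriptions, and log-CPM was chosen because raw-scale
  variance is dominated by expression level. Ties break lexicographically
  by gene id for determinism.

## 5. Methylation model

Evaluable CpGs have coverage ≥ 8; the coverage rule is applied per sample
record, and a cytosine is tested only when at least 3 samples per group
survive, which guarantees a well-posed design matrix (the source
methodology states only the per-read-coverage rule). With a single
two-level group factor, the binomial logistic regression has a closed-form
MLE — the coverage-weighted pooled proportion per group — so the
likelihood-ratio test against the intercept-only model is evaluated in
closed form; tests verify exact agreement with `glm(..., family =
binomial)`. q-values are Benjamini–Hochberg (the often-cited SLIM procedure
is not described in the motivating text; BH is the documented substitute).
A DMC requires a methylation change strictly greater than 20 percentage
points (pooled within-group proportions) and q ≤ 0.10.

Regions: gene body = the gene span (exons + introns); regulatory = a single
5.5-kb window upstream of the TSS (strand-aware); everything else
intergenic. A position in gene A's body and gene B's regulatory window is
annotated once per gene, since per-gene levels are computed independently.
CpGs are taken per strand as reported; symmetric CpG pairs are not merged.
Per gene and region, the methylation level is DMCs / evaluated cytosines;
a region with no evaluated cytosines is undefined (`NA`) and excluded
listwise from distribution tests and regressions.

## 6. Integration

The *differential coexpression score* of gene `g` is
`1 − cor(c_A(g), c_B(g))`, where `c_X(g)` is `g`'s correlation vector to
all other shared genes in condition X: 0 for identical coexpression, ~1
when the two patterns are unrelated. The quantity of this name in the
motivating analysis is never defined in its main text; this
correlation-vector definition is an implementation choice and the score
should be interpreted accordingly.

The preserved stratum pools the weak-to-moderate and strong classes.
KS comparisons are two-sample, two-sided. Regressions are untransformed OLS
with methylation level as the response — the published phrasing is
directionless and slope-sign conclusions are direction-invariant; no logit
transform or weighting is applied because none is described.

## 7. The synthetic-data generator

The generator is the validation bed and defines the study conditions:

- **Expression.** Gene `g` in module `m` has latent profile
  `sqrt(rho_g) z_m + sqrt(1 − rho_g) eps_g`, `rho_g` jittered ±0.12 around
  `within_module_cor` (0.7 by default) to create a connectivity gradient.
  Factor and noise profiles are standardized across samples so the planted
  correlation is realized at its nominal value rather than attenuated by
  finite-sample variance fluctuations. Latent profiles map through an
  exponential mean (amplitude 1.2 on the natural-log scale) to
  negative-binomial counts (dispersion 0.02 — residual technical noise on
  top of the planted biological signal) at library sizes of 0.8–1.2 M.
  Condition B redraws factors (preserved modules keep their loadings),
  replaces perturbed modules with independent noise (default; an
  `attenuate` mode scales loadings for graded tests — full destruction is
  the default because unpreserved modules in the motivating setting failed
  both density and connectivity), and leaves background genes independent
  throughout. Defaults mirror the study design: 9 vs 10 expression
  replicates, 7 vs 9 methylation replicates; validation runs use 20 + 20
  samples as specified for the recovery properties.
- **Annotation.** One synthetic chromosome, forward strand, non-overlapping
  gene models (1–4 exons) with 5.5-kb regulatory windows and intergenic
  gaps; 1-based inclusive coordinates. Strand complexity is out of
  analytical scope, but `assign_region()` is strand-aware for imported
  annotations.
- **Methylation.** CpGs are placed in bodies (~20/gene), regulatory windows
  (~8/gene) and intergenic gaps; per-sample coverage is uniform in 10–50
  with 5% of records forced below 8 to exercise the filter, and 5% of sites
  carry non-CpG contexts. A planted DMC shifts the group-B proportion by
  `meth_delta` (0.4), directed to stay inside (0, 1). The body DMC rate is
  multiplied by `perturbed_body_enrichment` (6) for perturbed-module genes
  — planting the body-methylation/preservation contrast — and, when
  `meth_kim_coupling > 0`, scaled by `exp(−coupling · z(rho_g))` in
  preserved modules, planting "more methylation ↔ less connectivity" there
  only. Effect sizes are free parameters of the generator, not calibrated
  to any particular dataset; they were fixed once at values a methylation
  study of this depth could plausibly show.

**What passing tests show — and don't.** The generator produces block
latent-factor modules, independent background genes, and binomial
methylation counts. Real data add correlated backgrounds, overlapping
modules, batch effects, coverage biases and spatially correlated
methylation, none of which are emulated. Green validation therefore
establishes that the algorithms are implemented correctly and recover
planted truth under the stated conditions — not that any particular
biological dataset will yield comparable power.

## 8. Problem sizes and numerical notes

Validation runs use 600 genes (6 × 50 module genes + 300 background),
20 samples per condition, 200–500 permutations, and ~20 000 cytosines —
sizes chosen so the full suite exercises every code path at interactive
speed while leaving the statistics well out of boundary regimes. Full
analyses scale as `O(n_genes²)` memory for adjacency/TOM and
`O(n_perm · Σ m_k²)` time for preservation.

Numerical conventions: Pearson correlations on log2-CPM; missing values are
input errors (no pairwise-complete handling); zero-variance genes are
rejected by name; `0·log 0 = 0` in the binomial likelihood; complete
separation is flagged rather than suppressed; permutation SDs of zero
produce flagged infinite Z scores excluded from medians; all generators and
permutation tests are bit-reproducible under a fixed seed.
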