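---
title: "Cell type-specific co-expression modules: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell type-specific co-expression modules: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Bulk co-expression analysis of brain tissue averages over cell types, so a
gene module that is tightly co-regulated in astrocytes but silent in neurons
is diluted or lost. `ctsnet` implements the converse strategy: build a
weighted gene co-expression network *separately for each cell type* of a
single-nucleus RNA-seq dataset, find the modules of each network, and then ask
three questions of every module:

1. Is it enriched with a disease candidate gene list (hypergeometric test,
   Benjamini–Hochberg FDR)?
2. Is it enriched with its own cell type's specific genes, and with no other
   type's (the top-N panel of a minimum-fold-change specificity score)?
3. Is there evidence that it is *not* preserved in the other cell types'
   networks (permutation Zsummary, median across test networks below 2)?

A module passing 1 and 2 is a *candidate* cell type-specific disease module;
passing 3 as well makes it *final*. The package ships a synthetic
single-nucleus generator with planted ground truth, so the whole pipeline is
exercised end-to-end against known answers.

## The synthetic study

`default_synth_config()` fixes the study conditions used by the package's
planted-truth evaluations:

* 3,000 genes, five cell classes with strongly unbalanced nucleus counts
  (800/400/200/120/80) — one dominant class, the skew typical of cortical
  snRNA-seq class compositions;
* negative-binomial counts around per-gene log-normal baseline means
  (median 5, log-sd 0.8) with one global dispersion 0.3 — the simplest
  overdispersed model adequate for the correlation-based downstream stages;
* 50 marker genes per class, 8-fold up-regulated in their class;
* three planted 60-gene modules: one active only in the astrocyte-like class
  and overlapping the disease list, one active in all classes and overlapping
  the disease list, one active only in the interneuron-like class with no
  disease overlap. Module co-expression is injected as a shared standard
  normal latent factor per nucleus, added on the natural-log mean scale with
  loading `latent_strength` (default 0.8) only in the active classes — this
  yields tunable Pearson correlation (about 0.45–0.55 on log counts at the
  default), which is exactly the statistic the network stage consumes;
* the disease list: 60% of each disease module plus 100 background genes;
* two sequencing batches with additive gene-by-batch shifts on the log-mean
  scale (sd 0.3) — the location-shift family the empirical-Bayes batch
  correction is designed to remove.

Planted modules are 60 genes rather than the minimum module size of 30
because highly-variable-gene selection is the gateway to the network stage: a
module restricted to a class holding an eighth of the nuclei only lifts the
*joint* variance of its genes weakly, so roughly 55–85% of its genes survive
HVG selection at FDR 0.1. Sixty genes keep the surviving core comfortably
above the detection threshold without making the module unrealistically
dominant.

What the generator deliberately does **not** emulate: dropout/zero inflation
beyond the negative binomial, doublets, ambient RNA, cell-cycle structure,
per-gene dispersions, and library-size confounding with cell class. Passing
the planted-truth evaluations therefore shows the statistical machinery works
when its model assumptions hold approximately; it does not certify behavior
under every artifact of real snRNA-seq data.

## Preprocessing

* **QC** (`qc_filter`): lower-tail outlier removal at 3 median absolute
  deviations on log library size and log detected genes — the standard
  scran-style rule; only the lower tail, since the generator has no doublets.
* **Normalization** (`size_factor_normalize`): library-size factors scaled to
  mean 1 (counts divided by factors, `log2(x+1)`). Pooling-based
  deconvolution is intentionally not implemented; downstream stages consume
  correlations, which are robust to this simplification.
* **Batch adjustment** (`correct_batch`): parametric empirical-Bayes
  location/scale correction — standardize per gene against the batch-design
  fit, shrink per-gene-per-batch means (normal prior) and variances
  (inverse-gamma prior) across genes with the standard iterative posterior
  updates (tolerance 1e-4, at most 100 iterations), adjust and restore. On a
  planted constant-shift simulation it agrees with the reference
  implementation in `sva` to near machine precision and removes ≥90% of the
  batch variance the generator plants.
* **HVG selection** (`select_hvgs`): per-gene variance against a robust loess
  trend of variance on mean (span 0.3, symmetric family); the biological
  component is total minus trend, tested one-sided with the analytic standard
  error of a sample variance under approximate normality,
  `trend * sqrt(2/(n-1))`, and BH-adjusted. At FDR 0.1 the empirical FDR on a
  calibrated Gaussian simulation stays within twice nominal. Selection runs
  on all nuclei jointly; per-class re-selection is not performed (networks
  use the global HVG list restricted to genes with nonzero variance in the
  class).

## Specificity

For gene *g* and type *c*, specificity is the minimum fold change of mean CPM
against every other type: `min_r (mean_c + eps) / (mean_r + eps)`. A
pseudocount `eps = 1` CPM in numerator and denominator keeps scores finite
for genes silent in a reference type; it is configurable and its effect
vanishes for well-expressed genes. The top 500 genes per type form that
type's specific-gene panel.

Two deliberate choices:

* The specificity universe defaults to **all** genes, not the HVG subset. The
  panel size (500) must be well below the universe for panel enrichment to
  discriminate; at desk scale the HVG universe is a few hundred genes and a
  top-500 panel would saturate it, making every panel test vacuous
  (`p = 1`). The `specificity_on = "hvg"` switch restores the other reading.
* An unclassified cell class can be excluded from both the interest and
  reference sets (`exclude_label`), so a mixed population does not
  contaminate the fold changes.

## Networks and modules

Per analyzed cell type (at least `min_nuclei = 30` nuclei — correlations from
fewer nuclei are too unstable to support a network):

1. Pearson correlation of the log-normalized HVG submatrix; zero-variance
   genes are dropped from that type's network only.
2. Soft power by scale-free fit: binned regression of `log10 p(k)` on
   `log10 k`, fit index signed by the slope; the smallest power in 1..10 with
   R² ≥ 0.8 wins, otherwise the conventional fallback 6 with a warning.
   Candidate powers stop at 10 because on networks of a few hundred genes the
   binned fit index is noisy and can cross the target spuriously at extreme
   powers (11+), which flattens the topological overlap and destroys module
   contrast; the fallback is the better-behaved choice there. The power is
   chosen independently per cell type and logged in the network summary.
3. Unsigned adjacency `|r|^beta`, then *signed* topological overlap: neighbor
   products keep correlation signs,
   `TOM_ij = |l_ij + s_ij a_ij| / (min(k_i,k_j) + 1 - a_ij)` with
   `l_ij = sum_u s_iu a_iu s_uj a_uj`.
4. Module detection by average-linkage clustering of `1 - TOM` with adaptive
   branch cutting: the dendrogram is cut at each height of a fixed grid (up
   to a `deep_split`-dependent ceiling, default 0.999) and the cut producing
   the most branches of at least `min_module_size = 30` genes is kept, ties
   resolved toward the higher cut. A cut where a single branch swallows more
   than 60% of the genes is rejected — that is the noise plateau congealing,
   not module structure. This replaces the published dynamic hybrid tree-cut
   algorithm with a simpler procedure validated by planted-partition
   recovery rather than label-for-label equivalence; the height grid is
   needed because the height at which branches complete depends strongly on
   the soft power.
5. Module eigengenes (first principal component of the standardized module
   submatrix, unit norm, sign-oriented positive against the module mean),
   merging of modules whose eigengene dissimilarity `1 - cor` falls below
   `merge_cut_height = 0.2` (iterated until stable), and kME pruning: genes
   with `|cor(gene, own eigengene)| < 0.2` are returned to the unassigned
   pool, after which eigengenes are recomputed once.

Ties in every ranking (panel membership, hub export) break lexicographically
by gene identifier, so all outputs are deterministic.

## Preservation

For a module found in a reference network, evaluated in a test network:

* density: mean off-diagonal adjacency of the module genes in the test
  network;
* connectivity: correlation of intramodular connectivity (ref vs test) and
  correlation of the vectorized within-module correlation entries (ref vs
  test).

The null is `n_perm = 100` random gene sets of the module's size from the
test network's universe (drawn from the full universe — excluding the
module's own genes changes little when the module is small relative to the
universe). `Zdensity` is the density Z; `Zconnectivity` the median of the two
connectivity Zs; `Zsummary` their mean. This is a three-statistic subset of
the published composite — density and connectivity, the two medians the
composite is built from — kept at desk scale; separability and
quality statistics are out of scope. A module's verdict uses the *median*
Zsummary across all test networks, with < 2 read as no evidence of
preservation (i.e. cell type-specific). A degenerate null (zero permutation
sd) flags the pair as not evaluable rather than producing an infinite Z.

## Enrichment and selection

Hypergeometric upper-tail tests run in log space via `phyper`. BH families
are per gene set, spanning all modules of all cell-type networks in a run:
one family for the disease list, one per specificity panel, one per GMT
collection — the most conservative reading consistent with applying the FDR
threshold per column of an enrichment matrix. The universe is the run's HVG
list; unassigned genes stay in the universe but are never tested as a
module. GMT annotation reports terms with `q < 0.1` and at least five genes,
counted as the module/term overlap by default (`min_genes_on = "term"`
switches to the term's universe size — the other reading of an ambiguous
rule). Term-redundancy removal is not performed.

## Problem sizes and runtime

The shipped evaluations run the default scenario (3,000 genes, 1,600 nuclei,
five networks of ~450–500 HVGs) in roughly ten seconds per seed on one core;
the planted-truth test suite repeats the key checks over ten seeds each.
These sizes were chosen so that a full multi-seed evaluation is an everyday
desk operation; they are an order of magnitude below the real study's
dimensions, which is why no numeric equivalence to any published table is
claimed — the evaluations are property-based (recovery, discrimination,
calibration, determinism) against planted truth.

## Known limitations

* The adaptive branch cut is a pragmatic stand-in for dynamic hybrid tree
  cutting; very close module pairs may merge or split differently.
* The scale-free fit index on small networks is noisy; the power cap and
  fallback make the choice stable but somewhat coarse.
* Specificity uses equal-weight minimum fold change only; other specificity
  metrics (expression proportions, enrichment-weighted scores) are not
  implemented.
* The preservation composite uses three statistics, not the full published
  set; absolute Zsummary values are therefore not comparable to other
  implementations, though the < 2 decision rule behaves as designed on
  planted truth.
* Batch correction assumes location/scale batch effects on log expression;
  count-model batch correction is out of scope.
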