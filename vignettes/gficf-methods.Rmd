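---
title: "Methods: gene frequency-inverse cell frequency for single-cell RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene frequency-inverse cell frequency for single-cell RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Droplet scRNA-seq produces a genes × cells matrix of UMI counts that is
extremely sparse and zero-inflated: most entries are zero, either because a
gene is silent or because a lowly expressed transcript dropped out of the
library. Word-occurrence matrices in text mining share exactly this shape,
and `scgficf` transplants the standard TF-IDF weighting to cells:

* **Gene frequency (GF).** Each cell's counts are divided by the cell's
  total UMI, `GF[i,j] = f[i,j] / sum_k f[k,j]`, so every cell sums to one.
  Because UMI counts are free of gene-length bias, this is a direct
  frequency, removing sequencing-depth differences between cells.
* **Inverse cell frequency (ICF).** Each gene is weighted by
  `ICF[i] = log(N / (n_i + 1))`, where `N` is the number of cells and
  `n_i` the number of cells in which gene `i` is detected (strictly
  positive count). Genes expressed in small subpopulations score high;
  ubiquitous housekeeping genes score near zero.
* **L2 normalization.** Each cell's weight vector `GF * ICF` is rescaled
  to unit Euclidean norm, removing residual magnitude differences.

Two readings of the smoothing term are typographically possible;
`add_one_denominator` (`log(N/(n_i+1))`, the standard smoothed inverse
frequency) is the default and `add_one_outside` (`log(N/n_i + 1)`) is
available as a config variant. The log base is natural; any base change is
a uniform positive scaling that cancels under the L2 step (verified by a
test).

**Negative ICF.** Under the default smoothing, a gene detected in *every*
cell has `ICF = log(N/(N+1)) < 0`. A negative "relevance" weight inverts
the meaning of the score, so the default policy clamps ICF at zero and
flags the gene (the recorded per-gene table keeps the formula value so the
invariant `icf = log(N/(n_i+1))` remains checkable). Setting
`allow_negative_icf = TRUE` keeps the literal formula. A cell whose
expressed genes all carry zero (clamped) ICF would become an all-zero
weight vector; `gficf_transform()` rejects such cells with an explicit
error rather than emitting a non-normalizable column.

## Downstream pipeline

1. **QC filtering.** Cells are retained when detected genes ≥ 500, total
   UMI ≥ 1,500 and mitochondrial UMI fraction ≤ 10% (all configurable;
   retention is inclusive at the boundary). Mitochondrial genes are found
   by id prefix (`MT-`/`mt-`) or an explicit id set. Genes are never
   filtered; all-zero genes are only flagged (`n_i = 0` is legal, giving
   the maximal weight `log(N)`).
2. **PCA meta-genes.** The cells × genes weight matrix is gene-wise
   mean-centered (no variance scaling — the L2 step already equalizes
   cells) and projected onto its top 50 principal axes. Component signs
   are fixed by forcing each component's largest-magnitude loading
   positive, for bitwise reproducibility across BLAS libraries.
3. **t-SNE.** The meta-genes feed an exact (O(n²)) t-SNE with perplexity
   30 and seed 0 by default, early exaggeration 12 for 250 of 1,000
   iterations, learning rate 200, momentum 0.5 → 0.8. No t-SNE package is
   available in this build, so the van der Maaten–Hinton algorithm is
   implemented in compiled code inside the package; identical seed and
   input give identical coordinates. UMAP is accepted as a method name for
   interface compatibility but raises an informative error, as no UMAP
   implementation is installable here and it is only an alternative
   embedder, never a quantitative claim.
4. **Rescaling.** Embedding axes are independently mapped to [-1, 1]
   (min → -1, max → +1; a degenerate axis maps to 0) before plotting and
   before intra-type distances, so distances are comparable across runs.
5. **Graph clustering.** On the rescaled 2-D coordinates (deliberately, to
   mirror the visualization space; meta-gene-space clustering is not the
   default), each cell's 50 Manhattan nearest neighbors are computed (self
   excluded, ties at the k-th distance broken by ascending cell index).
   Cells u, v that appear in at least one directed neighbor relation are
   joined by an edge weighted with the Jaccard coefficient of their two
   neighbor sets; zero-weight edges are dropped, and isolated cells become
   singleton clusters. Louvain community detection (igraph) partitions the
   graph; cluster ids are contiguous from 0 and the reported modularity is
   the standard weighted modularity of the returned partition.
6. **Signatures and annotation.** Per cluster, genes are ranked by the sum
   of their gf-icf weights over the cluster's cells; the top 100 genes with
   positive aggregate score (ties broken lexicographically) form the
   cluster signature. For every reference cell type in a bulk panel, genes
   are ranked by log2 fold-change of the type's mean expression versus the
   mean of all other types (pseudo-count 1) — a discriminative ranking is
   required for type-specific calls, and fold-change-versus-rest is the
   minimal standard choice. The signature is scored on each ranking with
   the classical GSEA running sum (hits advance by `|stat|^p`, `p = 1` by
   default, normalized over the set; misses retreat by `1/(n - hits)`; the
   score is the extremum of the running sum). A gene-label permutation
   null (1,000 draws; sample permutation is impossible in a
   signature-versus-ranking design) yields `NES = ES / mean(same-sign null
   ES)` and a permutation p-value. Each cluster is assigned the type with
   the highest NES — not the smallest p-value, which saturates at
   `1/(n_perm+1)` — with ties broken by raw ES, then type name.
7. **Evaluation.** Adjusted Rand index (Hubert–Arabie; binomial
   coefficients accumulate exactly in doubles far below 2^53), cluster
   purity, per-type mean pairwise Euclidean distance on the rescaled
   embedding (pairwise mean, not centroid-based, matching "distance among
   cells of the same type"; the overall summary is the unweighted mean
   across types so small types are not swamped, with a cell-weighted
   variant available; classes above 10^6 pairs are subsampled with a fixed
   seed), and per-cell annotation accuracy with an optional user-supplied
   label-grouping map.

## What the synthetic generator emulates

`simulate_counts()` draws, per cell, a depth uniform in 2,500–7,000 UMI,
multinomial counts over per-type expected proportions (log-normal baseline
rates, sd 1.8 on the log scale, with the type's markers multiplied by 8 and
the mitochondrial block scaled to a 1–8% target fraction), then an
expression-dependent dropout that zeroes an entry with probability
`plogis(-0.5 - log1p(expected count))`. The result has roughly two-thirds
zero entries, median ~680 detected genes and ~4,300 UMI per cell, and ~99%
of cells clear the default QC cut — a deliberately small but
distributionally realistic droplet experiment. Multinomial sampling
conditional on depth (rather than independent Poissons) keeps depth exactly
controlled, so the GF step is exercised against known proportions; a cell
zeroed out entirely by dropout has its largest entry restored so every cell
keeps depth ≥ 1.

Markers are sampled from genes with above-median baseline rate: a marker
must be detectably expressed to plant signal — an 8-fold elevation of a
gene that is never observed is unrecoverable by any method, and would make
"markers appear in the cluster signature" vacuously false. The matched bulk
panel (`simulate_reference_panel()`) places each type's markers at the top
of that type's fold-change ranking (exactly so at zero noise), emulating
FACS-purified reference profiles on the same gene namespace.

The generator does **not** emulate batch effects, ambient RNA, doublets,
trajectories, or the empirical distributions of any real dataset. A green
recovery test therefore establishes that the pipeline's machinery is
correct and sensitive at realistic sparseness — not that it reproduces
published accuracies on real PBMC-scale data, which require external
downloads and are out of scope.

## Numerical choices and edge cases

* Column normalizations carry tolerances of 1e-12 (GF sums) and 1e-9 (L2
  norms); sparse row scaling touches stored entries only, so the infinite
  ICF of an unexpressed gene under the `add_one_outside` variant never
  multiplies a structural zero.
* Duplicate embedding coordinates are legal; neighbor ties break by cell
  index, making the graph deterministic.
* An edgeless graph (every Jaccard weight zero) produces singleton
  clusters with a warning rather than an error.
* Empty signature–panel intersections annotate the cluster `"unassigned"`;
  an intersection below 20 genes warns.
* One global pipeline seed derives per-stage seeds from the stage name, so
  stages can be rerun in isolation; artifacts (including `run.log`, which
  deliberately carries no timestamp) are byte-identical across reruns with
  identical inputs and configuration.
* `sim_config(marker_fold = 1)` is the no-signal control: all types become
  exchangeable and clustering agreement with the planted labels collapses
  to chance (|ARI| < 0.05).

## Known limitations

* Exact t-SNE is O(n²) in memory and time; it is comfortable to tens of
  thousands of cells but has no Barnes–Hut acceleration.
* Clustering on 2-D embedding coordinates inherits t-SNE's distortions;
  a config switch to cluster in meta-gene space is a possible extension.
* Cross-species gene-id matching for annotation is out of scope; the panel
  must share the signature's namespace.
* No gene-level filtering (e.g., minimum cells per gene) is applied by
  default; none is needed because `n_i = 0` is handled downstream.
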