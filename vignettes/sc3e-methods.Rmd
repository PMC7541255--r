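---
title: "Graph-based selection of scRNA-seq preprocessing: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-based selection of scRNA-seq preprocessing: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sc3e)
```

## The problem

A genes × cells expression matrix can be handed to a consensus clustering
engine raw, log2(x+1)-transformed, per-gene z-scored, or passed through an
sctransform-style negative-binomial residual transform. These choices change
the cell-cell geometry the engine sees, and the best one depends on the data
set: a few high-magnitude genes argue for z-scoring, heavy technical noise
for variance stabilization, already-normalized units sometimes for nothing
at all. `sc3e` turns the choice into a measurement: run the engine under
each candidate and score the *internal consistency* of each result without
ever seeing ground truth.

## The consensus engine

The engine is a faithful re-implementation of the SC3 recipe, which this
package treats as a fixed, config-exposed black box:

1. **Gene filter** — drop genes detected (raw value > 0) in fewer than 6%
   or more than 94% of cells. Detection is always evaluated on the
   *untransformed* scale so all four preprocessed matrices keep the same
   gene set; z-scored values are nonzero where the raw matrix was zero, and
   filtering on them would be meaningless.
2. **Distances** — Euclidean, 1 − Pearson, 1 − Spearman between cell
   columns. Spearman is Pearson on per-column average ranks. A
   zero-variance column has no defined correlation; its distance to
   everything is set to 1, the uninformative midpoint of [0, 2].
3. **Embeddings** — PCA of the column-centered distance matrix, and the
   eigenvectors (ascending eigenvalue) of the symmetric normalized
   Laplacian of the kernel exp(−D/max D). The kernel is a documented,
   swappable choice; any bounded decreasing map of D behaves similarly. The
   trivial first Laplacian eigenvector is *kept*, matching the SC3
   convention of taking the first d eigenvectors wholesale. (It carries no
   sign split — separation lives in the Fiedler coordinate — but k-means is
   indifferent to a near-constant coordinate.)
4. **k-means grid** — embedding dimensions d = round(4%·n)..round(7%·n)
   (clamped to [2, n−1]; if the interval is empty at tiny n, d =
   min(n−1, k+1) with a warning). k-means uses k-means++ seeding,
   10 restarts, 300 iterations; each grid point's seed is a deterministic
   hash of the master seed, so the ensemble is reproducible and
   order-independent.
5. **Consensus** — c_ij = fraction of the (3 metrics × 2 embeddings × |d|)
   labelings placing i and j together; complete-linkage hierarchical
   clustering on 1 − c_ij, cut at k, labels renumbered by first appearance.

No claim is made of numeric agreement with the R `SC3` package (whose exact
parameterization varies by version); the recipe, not the bits, is what the
score consumes.

## The C-score

Given consensus C and labeling T, with thresholds α (default 0.6) and β
(default 0.5):

- in-cluster edge for a same-cluster pair with c_ij **strictly below** α;
- out-cluster edge for a different-cluster pair with c_ij **strictly
  above** β.

Ties at the threshold add no edge — the literal reading of "lower/higher
than", and a measure-zero event for real consensus values. Contraction
averages the exceedances: w_i = Σ(α − c)/k_i within cluster i (0 when
k_i = 0, including singleton clusters, which cannot form pairs),
d_ij = Σ(r − β)/|E_ij| between clusters, d_i the sum of d_ij over the
neighbors of cluster node i. W_in and D_out average w_i and d_i over *all*
cluster nodes — isolated nodes contribute zeros, because the defining sums
run over every cluster unconditionally — and the C-score is their product.

Two properties worth knowing:

- **The averaged scores are not monotone in the thresholds.** Raising α
  admits new in-cluster edges, which raises the numerator Σ(α − c) but also
  the denominator k_i, so w_i can drop (edges {c = 0.1} at α = 0.5 give
  w = 0.4; adding c = 0.54 at α = 0.55 gives 0.23). What is monotone, and
  what the property tests assert, is the edge sets themselves and the
  pre-averaging exceedance sums.
- **Zero is a degenerate score, not a perfect one.** A crisp consensus —
  whether crisply *right* or crisply *wrong* — crosses neither threshold,
  empties both edge sets, and scores exactly 0. With several methods at 0
  the score cannot discriminate, so the result carries a `zero_score` flag
  and the selection report a `zero_score_warning`. For very small data sets
  (≲100 cells) a higher α and lower β keep the graphs populated; the
  package surfaces the flag rather than auto-tuning. Ties at 0 fall back to
  the fixed priority below.

## Selection

Each method × repeat gets a seed hashed from (master seed, method name,
repeat index): adding a method or raising `N` never perturbs the other
runs, and a whole report is byte-reproducible from its inputs. Mean C-score
over `N` repeats is the selection statistic; `N = 1` is the default, with
`N = 3` a cheap stabilizer when methods score closely. Exact ties break by
log > zscore > none > sctransform — log first because it is the
field-standard default an undecided user would have applied anyway. A
method whose engine errors is marked failed and excluded. The reported
labels are those of the final repeat (the repeats differ only in ensemble
seeding; any of them is an equally valid representative, and the last is
the cheapest to keep).

The number of clusters k is a required input. The evaluation setting this
package addresses assumes cell types known a priori; estimating k is a
different problem and deliberately out of scope.

## The sctransform stand-in

The full sctransform fit (regularized per-gene NB regressions with kernel
smoothing of parameters over mean expression) is out of scope; the package
substitutes plain NB Pearson residuals under a multinomial null:
μ_ij = s_j · p_i with s_j the library size and p_i the gene's share of all
counts; θ_i by method of moments (Σμ² / (Σ(x−μ)² − Σμ), infinite i.e.
Poisson when the excess is non-positive), floored at θ_min = 0.01; residuals
clipped to ±√n. This preserves the two properties the selection pipeline
cares about — approximate per-gene unit variance (verified by Monte Carlo on
Poisson counts) and bounded influence of outlier cells — behind the same
`PreprocessedMatrix` interface a faithful port would use.

## The simulator: what it does and does not establish

`simulate_counts()` generates log-normal baseline gene means, per-cluster
fold changes of 2^(±LFC) on a random DE gene subset, NB counts (variance
μ + φμ²), uniform dropout, log-normal library-size factors, and unit
conversion (CPM/TPM/RPKM/FPKM/QN — quantile normalization via limma, whose
tie interpolation equalizes distributions only up to tied runs). Defaults
(90 cells, 2000 genes, 3 clusters, 10% DE at 2-fold, φ = 0.1, 10% dropout,
20% library CV) describe a small, clearly structured data set of the kind
used for desk-scale validation.

It deliberately omits batch effects, doublets, cell-cycle structure and
gene-gene correlation. A green test therefore establishes that the
pipeline's machinery is correct and that the C-score tracks clustering
quality *when the planted structure is the only structure* — it does not
certify performance on real tissues, where the score is known to be less
predictive for large, unstable data sets. `simulate_consensus()` skips the
engine entirely and plants a noisy block consensus matrix, giving the graph
scorer fixtures with exactly known geometry.

## Numerical choices

- ARI uses the contingency-table formula with exact integer-valued
  binomial coefficients (all below 2^53 for any realistic n, hence exact in
  doubles) and the convention that the degenerate 0/0 case (expected =
  maximum index) returns 1 for identical partitions, 0 otherwise. The
  worked micro-case ARI([1,1,2,2],[1,2,1,2]) = −1/2, confirmed by an
  independent pair-counting oracle.
- The graph scorer is verified against a brute-force pair-loop oracle to
  1e−12 on 500 random instances.
- Dense files are written with `%.17g`, so read(write(M)) is bit-for-bit;
  the MTX writer emits coordinate lines directly for the same reason.
- Seeds are confined with `withr::with_seed`; no function mutates the
  caller's RNG state.

## Known limitations

- The C-score measures consensus *stability*, not correctness: a
  confidently wrong clustering can score 0 (see the zero-score flag above).
  This is inherent to the index, not an implementation artifact.
- α/β are not auto-tuned; defaults follow the published values.
- Very large matrices are handled only by the `max_cells` subsampling cap
  (default 5000), not by a hybrid SVM mode.
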