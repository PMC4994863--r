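---
title: "Cluster-based MST pseudotime: model, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cluster-based MST pseudotime: model, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseudopath)
```

## The model

`pseudopath` assumes each cell's transcriptome Y is an appropriately
normalized G-dimensional expression vector (we never re-normalize library
sizes; apply `log_transform()` if the input is on a raw TPM/FPKM scale) and
that the population traces a gradual transition, so that cells close in the
underlying process are close in expression space. The ordering problem is
solved at the *cluster* level first: a Gaussian mixture groups cells into a
small number of states, a minimum spanning tree over the cluster centers
estimates the backbone of the transition, and individual cells are then
interpolated along the backbone by projection. Clustering before tree
building is the central design commitment: a tree over a handful of cluster
centers is vastly more stable under resampling than a tree over hundreds of
individual cells, at the price of assuming the process is adequately
summarized by a chain (or low-degree tree) of discrete states.

Pseudotime here is an integer rank along a path, not an arc-length. Two
cells' pseudotime difference therefore says nothing about the magnitude of
their expression difference, only their order.

## Preprocessing choices

* **Gene modules.** Genes with zero expression everywhere are dropped; the
  rest are grouped by complete-linkage hierarchical clustering on Euclidean
  distances into H = max(1, round(0.05 · G′)) modules (`cluster_genes()`,
  `fraction = 0.05`). Averaging within modules dilutes drop-out events —
  zeros in cells that do express a gene — because a module's other members
  carry the signal. The 5% value is a bias/variance compromise: fewer modules
  average away real heterogeneity, more modules stop protecting against
  dropout. Rounding is half-away-from-zero; the fraction applies to all
  nonzero genes (constant rows are only dropped later, at standardization).
* **Standardization and PCA.** Module rows are standardized to mean 0, SD 1
  across cells (zero-SD rows are dropped with a warning rather than producing
  NaN), and PCA treats cells as observations of the standardized module
  variables. Scores are not whitened. Each PC's sign is fixed by making its
  largest-magnitude loading positive, so results are reproducible across
  platforms; total explained variance equals the number of retained modules
  (trace conservation), which the tests verify.
* **Choosing K.** The scree v_i = sqrt(lambda_i) is fitted, for each
  candidate breakpoint k, by a continuous two-segment linear model
  parameterized as f(i) = a + b·(i−k) for i ≤ k and a + c·(i−k) for i > k —
  continuity at k holds by construction, so the constrained least-squares
  problem is an ordinary 3-column regression. The fit uses the first
  min(20, available) PCs with candidates k ∈ [2, m−1]; ties in residual sum
  of squares go to the smallest k (with a relative tolerance, so an exactly
  linear scree deterministically yields k = 2). The same fit applied to the
  k-means unexplained-variance curve selects the k-means cluster count
  (`select_kmeans_k()`), where candidates exclude only the last count so the
  degenerate all-identical-cells case returns the smallest candidate.

## Cell clustering

The default clusters cells with `mclust` (full per-component covariances,
"ellipsoidal, varying volume, shape and orientation"), choosing the component
count in 2..9 by BIC (mclust's convention: 2·logL − p·log N, maximized) and
assigning each cell to its maximum-posterior component. One-component
solutions are excluded because ordering needs at least two tree nodes; if
clustering nonetheless collapses to one cluster, `order_single_cluster()`
falls back to ordering by PC 1 with a prominent warning. For tree building,
cluster centers are always the *empirical* means of member cells'
coordinates, so the Gaussian-mixture, k-means and no-clustering variants are
handled uniformly; fitted component means are reported alongside. The
no-clustering variant (`method = "none"`, every cell its own cluster)
reproduces the cell-level-tree ablation and shows why clustering matters.

## Tree and ordering conventions

The MST is built by Prim's algorithm from the lowest-indexed node with
equal-length edges broken by the lexicographically smallest (min id, max id)
pair, so duplicate centers cannot make results run-dependent. The main path
maximizes cluster count, then member-cell count, then the lexicographically
smallest canonically-oriented sequence. The default origin is the lower-id
end of the main path — a deterministic stand-in for an arbitrary choice —
and can be overridden by an explicit `origin`, by a marker gene whose
least-squares trend along the path should be increasing or decreasing
(`orient_path()`), or by a fully manual cluster sequence validated against
the tree. Cell projections use the raw inner product with the unit edge
vector; equal projections are broken by stable input index. Branch paths
recompute projections independently of the main path. Marker trimming
removes a cell before ordering only when it exceeds *every* active
threshold (conjunction).

## Differential expression

Each gene is fitted by `mgcv::gam` with a fixed-flexibility smooth of
pseudotime, `s(pt, k = 3, fx = TRUE)` at the default `edf = 3`: an intercept
plus two smooth parameters. The likelihood-ratio statistic against the
constant model is referred to a chi-square whose df is the fitted model's
parameter count minus one (2 at the default) — computed from the fit, not
hard-coded. A fixed-df regression spline rather than a penalized smooth
keeps the reference distribution honest and the fit deterministic. The
Gaussian likelihood matches log-scale expression inputs; count models are
out of scope. P-values are step-up Benjamini–Hochberg adjusted (`fdr_adjust()`
wraps `p.adjust`; a q-value-style estimator would differ only by the pi0
factor). On 500 simulated null genes the empirical type-I error at 0.05 sits
inside the binomial 95% CI (the test suite checks this), though the
chi-square reference is asymptotic and can drift liberal below ~50 cells.
All p-values are conditional on the estimated ordering; propagating ordering
uncertainty into inference is an open problem and deliberately not attempted.

## Evaluation framework

POS normalizes the sum of signed pairwise time-index differences by
D = Σ_pairs |τ_a − τ_b|, the numerator attained by any time-sorted ordering —
hence the tight bound with POS = 1 at perfect agreement and −1 at exact
reversal, which an exhaustive permutation oracle confirms on small fixtures.
Same-time pairs contribute 0 to both numerator and bound. Time-point
*indices* (ranks of distinct labels) are the default weighting; raw label
differences are available via `weight = "raw"` for unequally spaced designs.
A single time point makes POS undefined; we return 0 with a warning.

The similarity score counts concordant unordered pairs over the *union* of
cells, with pairs touching a cell absent from either ordering counted as
discordant. Under x = 90% subsampling even a perfect pipeline is therefore
capped near x² ≈ 0.81 — robustness values must be compared between methods at
the same x, never read as absolute accuracy. Likewise, a pipeline that
ignores expression entirely is perfectly robust, so robustness complements
but never replaces POS. Cell counts in `perturb_cells()` round half away
from zero; `perturb_expression()` conserves per-gene means exactly and
inflates variance by about 1 + κ² in expectation. Robustness runs freeze
orientation and path choices from the original run's configuration and
re-apply them to each of the (default 100) replicates.

## The simulator

`simulate_trajectory()` emulates the structure the method assumes: latent
positions t ~ U(0,1); trend genes following linear, sigmoid or transient
shapes (half decreasing) with amplitudes U(2, 5) over baselines U(0.5, 2);
flat genes at baselines U(0.5, 3); Gaussian noise (default SD 1, moderate
relative to the 2–5 amplitudes); Bernoulli dropout with probability
`dropout_rate · exp(−expression)` (default rate 0.2), so high expression is
rarely lost; and collection-time labels from equal-width binning of t into
V = 4 time points, mirroring a typical 4-time-point differentiation design.
Because noise crosses bin edges, labels only roughly reflect the true order,
as in real time courses. With `branch = TRUE`, cells past the branch point
split into two lineages and trend genes cycle through shared /
lineage-1-specific / lineage-2-specific groups, the lineage-specific ones
silent before the branch and ramping up only in their lineage — divergence is
in expression space, not merely in labels. Defaults (300 cells, 500 genes,
100 trend genes) were fixed once as a realistic desk-scale study and are the
conditions under which the end-to-end recovery test runs: POS ≥ 0.8 against
the time bins and a strict win over a single-noisy-marker baseline. The
bifurcation tests fix the cluster count (e.g. 5) because BIC on a compact
Y-shaped manifold can legitimately prefer a 3-component chain that folds the
two tips into one elongated component.

What the simulator does *not* emulate: count-level sampling (negative
binomial), library-size effects, batch structure, doublets, or
transcriptome-wide correlation beyond the trend/flat dichotomy. Passing
tests on it demonstrates the algorithmic contracts, not performance on any
particular real dataset.

## Problem sizes and determinism

The test suite and the acceptance script run on simulations of 100–500 cells
and 150–2000 genes — sizes at which every stage completes in seconds and
small enough for brute-force oracles (exhaustive spanning trees, all 720
permutations of 6 cells) to verify the implementations. A single global seed
fans out to per-stage seeds (clustering uses seed + 1, per-replicate
perturbations seed + r), so identical configurations produce byte-identical
artifacts; the pipeline writes a manifest recording version, seed and the
full configuration next to its outputs.

## Known limitations

* A minimum spanning tree cannot represent cycles or convergent lineages.
* BIC may merge branch tips into elongated components (see above); for
  known-branched data, fix `n_clusters`.
* Integer pseudotime carries no rate information.
* DE inference ignores ordering uncertainty.
* POS requires external labels at ≥ 2 time points and assumes they roughly
  track the biological order.
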