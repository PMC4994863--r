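# pseudopath

Pseudotime reconstruction for single-cell RNA-seq by cluster-based minimum
spanning trees, with a quantitative evaluation framework for comparing cell
orderings.

## The problem

Cells sampled from a differentiating or responding population are snapshots
of a continuous process. Pseudotime reconstruction places the cells in an
order that reflects their gradual transcriptome transition, so that gene
dynamics along the process can be studied without knowing each cell's true
stage. `pseudopath` is aimed at analysts with a normalized genes × cells
expression matrix (e.g. log2(TPM+1)) who want a reproducible, scriptable
ordering plus objective numbers for judging how good that ordering is.

## The method

Cells are ordered in three steps:

1. **Preprocess.** Genes with all-zero expression are removed; the remaining
   genes are grouped into modules by hierarchical clustering (Euclidean
   distance, complete linkage), with the module count set to 5% of the
   nonzero genes. Module-averaged expression is row-standardized and reduced
   by PCA. The number of retained components K is chosen by fitting, for each
   candidate breakpoint k, a continuous two-segment linear model to the scree
   values v_i = sqrt(lambda_i) and minimizing the residual sum of squares.
   Module averaging stabilizes the signal against drop-out events.
2. **Cluster and connect.** Cells are clustered in PC space with a Gaussian
   mixture model with full per-component covariances; the number of
   components is chosen by BIC. A minimum spanning tree under Euclidean edge
   lengths connects the cluster centers. The *main path* is the leaf-to-leaf
   path with the most clusters (ties: most cells); all other origin-to-leaf
   paths are branch paths.
3. **Project and order.** Each cell is projected onto a tree edge of its
   cluster's segment of the path via the inner product with the unit edge
   vector, and cells are sorted by (cluster position, edge, projection).
   The rank of a cell in this order is its integer pseudotime.

Downstream, each gene is tested for differential expression along pseudotime
by a likelihood-ratio test of a fixed-flexibility spline smooth (effective
df = 3) against a constant model, with Benjamini–Hochberg FDR control.

Orderings are evaluated by:

- **POS** (pseudo-temporal ordering score): normalized sum of signed pairwise
  time-index differences against external collection-time labels; 1 = perfect
  agreement, −1 = exact reversal.
- **Similarity score**: fraction of unordered cell pairs whose relative order
  two orderings share (pairs missing from either ordering count as
  discordant), used with cell-subsampling and permuted-residual perturbations
  (100 replicates by default) to measure robustness.
- **Gold-standard gene ranking**: mean rank and top-R counts of independently
  known dynamic genes in the differential-expression ranking.

## Worked example

Everything runs on simulated data with known truth — no downloads needed:

```r
library(pseudopath)

sim <- simulate_trajectory(seed = 46)   # 300 cells, 500 genes, 4 time points
cfg <- run_config(seed = 46, marker = "gene_0001",
                  marker_direction = "increasing")
res <- run_pipeline(sim$matrix, cfg)

res$model$n_clusters                    # 3
res$main_path$cluster_sequence          # 1 2 3
res$pos                                 # 0.996

base <- marker_only_ordering(sim$matrix, "gene_0001", "increasing")
pos_score(base$cell_order, sim$matrix$collection_time)   # 0.809

sum(res$de$differential)                # 108 genes at FDR < 0.05
gold_gene_metrics(res$de, sim$trend_genes,
                  top_grid = c(100, 200))$mean_rank      # 50.5
```

The full pipeline's ordering agrees almost perfectly with the simulated
collection times (POS 0.996) and clearly beats ordering by a single noisy
marker gene (POS 0.809). The 100 simulated trend genes occupy exactly the
top 100 ranks of the differential-expression table (mean rank 50.5), and 108
genes pass FDR < 0.05 — the 100 real trends plus a handful of borderline
false positives, consistent with the 5% FDR target.

A thin command-line wrapper with `simulate`, `run` and `evaluate`
subcommands is installed at `inst/scripts/pseudopath-cli.R`:

```sh
Rscript inst/scripts/pseudopath-cli.R simulate --out sim --seed 1
Rscript inst/scripts/pseudopath-cli.R run --input sim/expression.tsv \
    --time sim/collection_time.tsv --out run1 --seed 1
```

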