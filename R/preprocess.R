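#' Drop genes with zero expression in every cell
#'
#' @param m an [expression_matrix()].
#' @return the matrix restricted to genes with at least one nonzero value,
#'   original gene order preserved.
#' @export
filter_zero_genes <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  keep <- rowSums(m$values != 0) > 0
  if (!any(keep)) stop("empty matrix after filtering: all genes are zero")
  expression_matrix(m$values[keep, , drop = FALSE],
                    gene_ids = m$gene_ids[keep], cell_ids = m$cell_ids,
                    collection_time = m$collection_time)
}

# round half away from zero (base round() rounds half to even)
round_half_up <- function(x) floor(x + 0.5)

#' Group genes into expression modules by hierarchical clustering
#'
#' Genes with similar expression patterns are grouped by agglomerative
#' hierarchical clustering (Euclidean distance, complete linkage) and the tree
#' is cut into H = max(1, round(fraction * G)) clusters, where G is the number
#' of genes. Averaging expression within these modules (see
#' [aggregate_gene_clusters()]) stabilizes the signal against drop-out events,
#' where an expressed gene registers a zero count because its molecules were
#' not captured.
#'
#' @param m an [expression_matrix()], already zero-filtered, with >= 2 genes.
#' @param fraction target number of clusters as a fraction of the number of
#'   genes (default 0.05, i.e. 5 percent).
#' @return a list of class `gene_clustering` with `n_clusters`, `labels`
#'   (named integer vector over genes) and `member_lists`.
#' @export
cluster_genes <- function(m, fraction = 0.05) {
  stopifnot(inherits(m, "expression_matrix"))
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must be in (0, 1]")
  g <- nrow(m$values)
  if (g < 2) stop("need at least 2 genes to cluster")
  h <- max(1L, as.integer(round_half_up(fraction * g)))
  hc <- stats::hclust(stats::dist(m$values, method = "euclidean"),
                      method = "complete")
  labels <- stats::cutree(hc, k = h)
  names(labels) <- m$gene_ids
  structure(list(n_clusters = h, labels = labels,
                 member_lists = split(m$gene_ids, labels)),
            class = "gene_clustering")
}

#' Average expression within gene clusters
#'
#' @param m an [expression_matrix()].
#' @param gc a [cluster_genes()] result covering all genes of `m`.
#' @return a list of class `aggregated_matrix` with `values` (H x N matrix of
#'   per-cluster, per-cell means), `cluster_ids` and `cell_ids`.
#' @export
aggregate_gene_clusters <- function(m, gc) {
  stopifnot(inherits(m, "expression_matrix"), inherits(gc, "gene_clustering"))
  if (!setequal(names(gc$labels), m$gene_ids)) {
    stop("gene clustering does not cover the genes of the matrix")
  }
  lab <- gc$labels[m$gene_ids]
  agg <- rowsum(m$values, group = lab, reorder = TRUE)
  agg <- agg / as.vector(table(lab)[rownames(agg)])
  cluster_ids <- paste0("module_", rownames(agg))
  rownames(agg) <- cluster_ids
  structure(list(values = agg, cluster_ids = cluster_ids,
                 cell_ids = m$cell_ids),
            class = "aggregated_matrix")
}

# continuous two-segment linear fit with breakpoint at x = k:
# f(x) = a + b*(x-k) for x <= k, a + c*(x-k) for x > k; continuity holds by
# construction. Returns the residual sum of squares.
two_segment_sse <- function(x, y, k) {
  X <- cbind(1, pmin(x - k, 0), pmax(x - k, 0))
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

# smallest candidate breakpoint attaining the minimal SSE (with a relative
# tolerance so exact ties are not broken by floating-point noise)
choose_breakpoint <- function(x, y, candidates) {
  sse <- vapply(candidates, function(k) two_segment_sse(x, y, k), numeric(1))
  tol <- 1e-9 * max(sum((y - mean(y))^2), .Machine$double.eps)
  best <- candidates[which(sse <= min(sse) + tol)[1]]
  list(k = best, sse = stats::setNames(sse, candidates))
}

#' Choose the number of principal components from a scree vector
#'
#' Fits, for every candidate breakpoint k, a continuous piecewise-linear model
#' with two segments to the scree values v_i (square roots of the variance
#' explained by successive PCs) and returns the k with the smallest residual
#' sum of squares; ties go to the smallest k. The breakpoint marks where the
#' scree flattens into the noise floor, so the first k components are kept.
#'
#' @param v non-increasing numeric vector of scree values, length >= 4.
#' @param k_min smallest candidate breakpoint (default 2).
#' @return the selected integer k. Attributes `sse` (per-candidate residual
#'   sum of squares) and `fit_params` (a, b, c of the winning fit) are set.
#' @export
choose_num_pcs <- function(v, k_min = 2) {
  m <- length(v)
  if (m < 4) stop("need at least 4 scree values")
  if (any(diff(v) > 1e-8 * max(abs(v), 1))) {
    stop("scree vector must be non-increasing")
  }
  idx <- seq_len(m)
  res <- choose_breakpoint(idx, v, seq.int(k_min, m - 1L))
  k <- res$k
  X <- cbind(1, pmin(idx - k, 0), pmax(idx - k, 0))
  coefs <- stats::lm.fit(X, v)$coefficients
  structure(as.integer(k), sse = res$sse,
            fit_params = c(a = unname(coefs[1]), b = unname(coefs[2]),
                           c = unname(coefs[3])))
}

#' Standardize, run PCA and retain the leading components
#'
#' Each row (gene module) of the aggregated matrix is standardized to zero
#' mean and unit standard deviation across cells; constant rows are dropped
#' with a warning. PCA then treats cells as observations and standardized
#' modules as variables. The scree is built from the leading components and
#' the number retained, K, is chosen by [choose_num_pcs()] unless overridden.
#' Each PC's sign is fixed so its largest-magnitude loading is positive.
#'
#' @param a an [aggregate_gene_clusters()] result with >= 2 modules and >= 3
#'   cells.
#' @param max_pcs_for_fit number of leading PCs used for the scree fit
#'   (default 20, truncated to the number available).
#' @param k_override retain exactly this many PCs instead of fitting the
#'   scree model.
#' @return a list of class `reduced_matrix` with `coords` (N x K PC scores),
#'   `loadings` (modules x K), and `scree` (list with `v`, `lambda`,
#'   `chosen_k`, `per_k_sse`, `fit_params`).
#' @export
reduce_dimension <- function(a, max_pcs_for_fit = 20, k_override = NULL) {
  stopifnot(inherits(a, "aggregated_matrix"))
  n <- length(a$cell_ids)
  if (n < 3) stop("need at least 3 cells")
  if (nrow(a$values) < 2) stop("need at least 2 gene modules")
  sds <- apply(a$values, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant gene module(s) dropped before PCA")
  }
  vals <- a$values[sds > 0, , drop = FALSE]
  std <- (vals - rowMeans(vals)) / apply(vals, 1, stats::sd)
  pca <- stats::prcomp(t(std), center = FALSE, scale. = FALSE)
  # fix PC signs: largest-magnitude loading positive
  for (j in seq_len(ncol(pca$rotation))) {
    i <- which.max(abs(pca$rotation[, j]))
    if (pca$rotation[i, j] < 0) {
      pca$rotation[, j] <- -pca$rotation[, j]
      pca$x[, j] <- -pca$x[, j]
    }
  }
  lambda <- pca$sdev^2
  avail <- sum(pca$sdev > max(pca$sdev) * 1e-10)
  m <- min(max_pcs_for_fit, avail)
  v <- sqrt(lambda[seq_len(m)])
  if (!is.null(k_override)) {
    k <- as.integer(k_override)
    if (k < 1 || k > avail) stop("k_override out of range")
    scree <- list(v = v, lambda = lambda[seq_len(m)], chosen_k = k,
                  per_k_sse = NULL, fit_params = NULL)
  } else {
    if (m < 4) {
      stop("only ", m, " usable PCs: too few for the scree fit; ",
           "supply k_override")
    }
    k <- choose_num_pcs(v)
    scree <- list(v = v, lambda = lambda[seq_len(m)], chosen_k = as.integer(k),
                  per_k_sse = attr(k, "sse"),
                  fit_params = attr(k, "fit_params"))
    k <- as.integer(k)
  }
  coords <- pca$x[, seq_len(k), drop = FALSE]
  rownames(coords) <- a$cell_ids
  structure(list(coords = coords,
                 loadings = pca$rotation[, seq_len(k), drop = FALSE],
                 scree = scree, cell_ids = a$cell_ids),
            class = "reduced_matrix")
}

#' Full preprocessing: filter, gene-cluster, aggregate, reduce
#'
#' Convenience wrapper running [filter_zero_genes()], [cluster_genes()],
#' [aggregate_gene_clusters()] and [reduce_dimension()] in sequence.
#'
#' @inheritParams cluster_genes
#' @inheritParams reduce_dimension
#' @return a `reduced_matrix`; the intermediate `gene_clustering` and
#'   `aggregated_matrix` are attached as attributes.
#' @export
preprocess <- function(m, fraction = 0.05, max_pcs_for_fit = 20,
                       k_override = NULL) {
  mf <- filter_zero_genes(m)
  gc <- cluster_genes(mf, fraction = fraction)
  agg <- aggregate_gene_clusters(mf, gc)
  red <- reduce_dimension(agg, max_pcs_for_fit = max_pcs_for_fit,
                          k_override = k_override)
  attr(red, "gene_clustering") <- gc
  attr(red, "aggregated") <- agg
  red
}
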