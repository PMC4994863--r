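#' Cluster cells in the reduced expression space
#'
#' The default method fits a mixture of multivariate normal distributions with
#' unconstrained, per-component covariances ("ellipsoidal, varying volume,
#' shape and orientation") via [mclust::Mclust()], choosing the number of
#' components by BIC over `candidate_range` and assigning each cell to the
#' component with the largest posterior probability. `kmeans` replaces the
#' mixture with Lloyd's algorithm (cluster count from `n_clusters` or
#' [select_kmeans_k()]); `none` skips clustering entirely, making every cell
#' its own cluster so the spanning tree connects individual cells.
#'
#' Cluster centers used downstream for tree construction are always the
#' empirical means of the member cells' coordinates, so all three methods are
#' handled uniformly; for the mixture model the fitted component means are
#' also reported (`model_means`).
#'
#' @param r a [reduce_dimension()] result.
#' @param method `"gmm"` (default), `"kmeans"` or `"none"`.
#' @param n_clusters fixed number of clusters, bypassing model selection.
#' @param candidate_range integer vector of candidate cluster counts
#'   (default `2:9`).
#' @param seed integer seed for stochastic initialization.
#' @return a list of class `cell_cluster_model` with `method`, `n_clusters`,
#'   `labels` (named integer vector), `centers` (empirical means),
#'   `cells_per_cluster`, and for gmm also `posterior`, `bic_trace`,
#'   `model_means` and `loglik`.
#' @export
cluster_cells <- function(r, method = c("gmm", "kmeans", "none"),
                          n_clusters = NULL, candidate_range = 2:9,
                          seed = 1L) {
  stopifnot(inherits(r, "reduced_matrix"))
  method <- match.arg(method)
  x <- r$coords
  n <- nrow(x)
  if (method == "none") {
    labels <- stats::setNames(seq_len(n), rownames(x))
    centers <- x
    rownames(centers) <- as.character(seq_len(n))
    return(structure(list(method = "none", n_clusters = n, labels = labels,
                          centers = centers,
                          cells_per_cluster = table(labels)),
                     class = "cell_cluster_model"))
  }
  if (is.null(n_clusters) && n <= max(candidate_range)) {
    stop("need more cells than the largest candidate cluster count")
  }
  if (method == "gmm") {
    g <- if (!is.null(n_clusters)) n_clusters else candidate_range
    mn <- if (ncol(x) == 1) "V" else "VVV"
    set.seed(seed)
    fit <- tryCatch(
      mclust::Mclust(x, G = g, modelNames = mn, verbose = FALSE),
      error = function(e) NULL)
    if (is.null(fit)) {
      stop("Gaussian mixture fit failed for every candidate cluster count; ",
           "try method = \"kmeans\"")
    }
    labels <- stats::setNames(as.integer(fit$classification), rownames(x))
    bic <- fit$BIC[, 1]
    names(bic) <- rownames(fit$BIC)
    out <- list(method = "gmm", n_clusters = fit$G, labels = labels,
                posterior = fit$z, bic_trace = bic,
                model_means = t(fit$parameters$mean), loglik = fit$loglik)
  } else {
    k <- if (!is.null(n_clusters)) n_clusters else {
      select_kmeans_k(r, candidate_range = candidate_range, seed = seed)
    }
    set.seed(seed)
    km <- stats::kmeans(x, centers = k, nstart = 10, iter.max = 100)
    labels <- stats::setNames(as.integer(km$cluster), rownames(x))
    out <- list(method = "kmeans", n_clusters = k, labels = labels)
  }
  centers <- t(vapply(seq_len(out$n_clusters), function(cl) {
    colMeans(x[labels == cl, , drop = FALSE])
  }, numeric(ncol(x))))
  rownames(centers) <- as.character(seq_len(out$n_clusters))
  out$centers <- centers
  out$cells_per_cluster <- table(factor(labels, levels = seq_len(out$n_clusters)))
  structure(out, class = "cell_cluster_model")
}

#' Choose the k-means cluster count from the unexplained-variance curve
#'
#' For each candidate count, runs k-means and records the proportion of total
#' data variance left unexplained by the partition (within-cluster sum of
#' squares over total sum of squares). The same continuous two-segment linear
#' model used for scree-based PC selection is then fitted to this curve over
#' the candidate counts, and the breakpoint is returned.
#'
#' @inheritParams cluster_cells
#' @return the selected integer cluster count. Attribute `unexplained` holds
#'   the per-candidate curve.
#' @export
select_kmeans_k <- function(r, candidate_range = 2:9, seed = 1L) {
  stopifnot(inherits(r, "reduced_matrix"))
  x <- r$coords
  if (nrow(x) <= max(candidate_range)) {
    stop("need more cells than the largest candidate cluster count")
  }
  totss <- sum(scale(x, scale = FALSE)^2)
  if (totss <= 0) {
    # identical cells: every partition explains all (zero) variance
    return(structure(as.integer(min(candidate_range)),
                     unexplained = stats::setNames(
                       rep(0, length(candidate_range)), candidate_range)))
  }
  set.seed(seed)
  unexpl <- vapply(candidate_range, function(k) {
    km <- tryCatch(stats::kmeans(x, centers = k, nstart = 10, iter.max = 100),
                   error = function(e) NULL)
    # k exceeding the number of distinct points leaves nothing unexplained
    if (is.null(km)) 0 else km$tot.withinss / km$totss
  }, numeric(1))
  cand <- candidate_range[-length(candidate_range)]
  res <- choose_breakpoint(candidate_range, unexpl, cand)
  structure(as.integer(res$k),
            unexplained = stats::setNames(unexpl, candidate_range))
}
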