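#' Convert collection-time labels to time-point indices
#'
#' Distinct labels are ranked ascending and each cell receives the index of
#' its time point (1..V). Numeric labels sort numerically, character labels
#' lexicographically.
#'
#' @param labels named per-cell collection-time labels.
#' @return named integer vector of time-point indices; attribute `V` holds the
#'   number of distinct time points.
#' @export
time_indices <- function(labels) {
  if (is.null(labels)) stop("no collection-time labels")
  lev <- sort(unique(labels))
  tau <- match(labels, lev)
  names(tau) <- names(labels)
  structure(as.integer(tau), names = names(labels), V = length(lev))
}

# tau vector (and D denominator) for an ordering against labels
pos_parts <- function(ordering, labels, weight = c("index", "raw")) {
  weight <- match.arg(weight)
  if (anyDuplicated(ordering)) stop("ordering contains duplicate cells")
  miss <- setdiff(ordering, names(labels))
  if (length(miss)) stop("no time label for cell(s): ",
                         paste(utils::head(miss, 5), collapse = ", "))
  tau <- if (weight == "index") {
    as.numeric(time_indices(labels)[ordering])
  } else {
    as.numeric(labels[ordering])
  }
  n <- length(tau)
  w <- 2 * seq_len(n) - n - 1          # pair-count weights
  num <- sum(tau * w)                  # sum over i<j of tau_j - tau_i
  d <- sum(sort(tau) * w)              # tight bound: numerator when sorted
  list(tau = tau, numerator = num, D = d)
}

#' Pseudo-temporal ordering score (POS)
#'
#' Scores an ordering of cells against external collection-time information.
#' Every ordered pair (i before j) contributes the signed difference of the
#' two cells' time-point indices (zero for same-time pairs); the sum is
#' normalized by D, the value attained by any time-sorted ordering, so the
#' score lies in [-1, 1] with 1 for perfect agreement and -1 for the exact
#' opposite direction. If all cells share one time point (D = 0) the score is
#' defined as 0 with a warning.
#'
#' @param ordering character vector of cell ids in pseudo-temporal order.
#' @param labels named per-cell collection-time labels covering the ordering.
#' @param weight `"index"` (default) uses time-point indices 1..V for the
#'   pairwise differences; `"raw"` uses the raw numeric labels.
#' @return the POS score.
#' @export
pos_score <- function(ordering, labels, weight = c("index", "raw")) {
  parts <- pos_parts(ordering, labels, weight)
  if (parts$D == 0) {
    warning("all cells share one time point; POS undefined, returning 0")
    return(0)
  }
  parts$numerator / parts$D
}

#' Pairwise contribution of one cell pair to the POS score
#'
#' Returns g(pi, i, j) = (tau_j - tau_i) / D for the cells at positions `i` <
#' `j` of the ordering: 0 when the two cells were collected at the same time
#' point, positive when the later-collected cell is ordered later, negative
#' otherwise.
#'
#' @inheritParams pos_score
#' @param i,j positions in the ordering, `i < j`.
#' @return the pairwise score g.
#' @export
pos_pair_score <- function(ordering, labels, i, j,
                           weight = c("index", "raw")) {
  stopifnot(i >= 1, j <= length(ordering), i < j)
  parts <- pos_parts(ordering, labels, weight)
  if (parts$D == 0) {
    warning("all cells share one time point; pairwise score undefined, 0")
    return(0)
  }
  (parts$tau[j] - parts$tau[i]) / parts$D
}

#' Similarity score between two cell orderings
#'
#' The fraction of unordered cell pairs, over the union A of cells appearing
#' in either ordering, whose relative order is identical in both. A pair with
#' a cell missing from either ordering counts as discordant, so orderings over
#' disjoint cell sets score 0 and identical orderings score 1.
#'
#' @param pi1,pi2 character vectors of cell ids, each duplicate-free.
#' @return similarity in [0, 1].
#' @export
similarity_score <- function(pi1, pi2) {
  if (anyDuplicated(pi1) || anyDuplicated(pi2)) {
    stop("orderings must be duplicate-free")
  }
  a <- union(pi1, pi2)
  n <- length(a)
  if (n < 2) stop("need at least 2 distinct cells across the two orderings")
  p1 <- match(a, pi1)
  p2 <- match(a, pi2)
  both <- which(!is.na(p1) & !is.na(p2))
  concordant <- 0L
  if (length(both) >= 2) {
    q1 <- p1[both]; q2 <- p2[both]
    s1 <- sign(outer(q1, q1, "-"))
    s2 <- sign(outer(q2, q2, "-"))
    concordant <- sum(s1 == s2 & upper.tri(s1))
  }
  2 * concordant / (n * (n - 1))
}

#' Cell-level perturbation: random subsampling of cells
#'
#' Retains a uniformly sampled subset of round(x * N) cells (half away from
#' zero rounding) without replacement; each retained cell's expression profile
#' is unchanged and the original relative cell order is preserved.
#'
#' @param m an [expression_matrix()].
#' @param x fraction of cells to retain, in (0, 1].
#' @param seed integer seed.
#' @return the subsampled `expression_matrix`.
#' @export
perturb_cells <- function(m, x, seed = 1L) {
  stopifnot(inherits(m, "expression_matrix"))
  if (!(x > 0 && x <= 1)) stop("x must be in (0, 1]")
  n <- length(m$cell_ids)
  keep_n <- as.integer(round_half_up(x * n))
  if (keep_n < 3) stop("fewer than 3 cells would remain")
  set.seed(seed)
  keep <- sort(sample.int(n, keep_n))
  subset_cells(m, keep)
}

#' Expression-level perturbation: permuted scaled residuals
#'
#' For each gene, the mean across cells is subtracted to obtain residuals;
#' the residuals are scaled by `kappa`, permuted across cells (independently
#' per gene), and added back to the original values. All cells are retained
#' and per-gene means are conserved exactly.
#'
#' @param m an [expression_matrix()].
#' @param kappa residual scaling factor, >= 0 (0 returns the input unchanged).
#' @param seed integer seed.
#' @return the perturbed `expression_matrix`.
#' @export
perturb_expression <- function(m, kappa, seed = 1L) {
  stopifnot(inherits(m, "expression_matrix"))
  if (kappa < 0) stop("kappa must be >= 0")
  if (kappa == 0) return(m)
  set.seed(seed)
  n <- ncol(m$values)
  vals <- m$values
  for (g in seq_len(nrow(vals))) {
    r <- vals[g, ] - mean(vals[g, ])
    vals[g, ] <- vals[g, ] + kappa * r[sample.int(n)]
  }
  expression_matrix(vals, gene_ids = m$gene_ids, cell_ids = m$cell_ids,
                    collection_time = m$collection_time)
}

#' Perturbation configuration
#'
#' @param scheme `"cell"` (subsampling) or `"expression"` (permuted scaled
#'   residuals).
#' @param x retained-cell fraction (cell scheme; default 0.95).
#' @param kappa residual scale (expression scheme; default 0.1).
#' @param n_replicates number of independent perturbations (default 100).
#' @param seed base seed; replicate r uses `seed + r`.
#' @return a list of class `perturbation_config`.
#' @export
perturbation_config <- function(scheme = c("cell", "expression"), x = 0.95,
                                kappa = 0.1, n_replicates = 100, seed = 1L) {
  scheme <- match.arg(scheme)
  stopifnot(n_replicates >= 1)
  structure(list(scheme = scheme, x = x, kappa = kappa,
                 n_replicates = n_replicates, seed = as.integer(seed)),
            class = "perturbation_config")
}

#' Robustness of an ordering pipeline under data perturbation
#'
#' Runs the supplied ordering pipeline on the original data, then on
#' `n_replicates` independently perturbed copies, and scores each replicate
#' ordering against the original with [similarity_score()]. Replicates whose
#' pipeline fails are excluded from the mean with a warning. Note that
#' robustness alone does not certify accuracy: a pipeline that ignores the
#' expression data entirely is perfectly robust.
#'
#' @param m an [expression_matrix()].
#' @param pipeline function taking an `expression_matrix` and returning an
#'   `ordered_path` (or a character vector of ordered cell ids).
#' @param cfg a [perturbation_config()].
#' @return list with `similarity_mean`, `per_replicate` (length
#'   `n_replicates`, `NA` for failed replicates) and `n_failed`.
#' @export
robustness <- function(m, pipeline, cfg = perturbation_config()) {
  stopifnot(inherits(m, "expression_matrix"),
            inherits(cfg, "perturbation_config"))
  as_order <- function(res) {
    if (inherits(res, "ordered_path")) res$cell_order else as.character(res)
  }
  base <- as_order(pipeline(m))
  sims <- vapply(seq_len(cfg$n_replicates), function(rep) {
    pm <- if (cfg$scheme == "cell") {
      perturb_cells(m, cfg$x, seed = cfg$seed + rep)
    } else {
      perturb_expression(m, cfg$kappa, seed = cfg$seed + rep)
    }
    ord <- tryCatch(as_order(pipeline(pm)), error = function(e) NULL)
    if (is.null(ord)) NA_real_ else similarity_score(base, ord)
  }, numeric(1))
  n_failed <- sum(is.na(sims))
  if (n_failed > 0) {
    warning(n_failed, " replicate(s) failed and were excluded from the mean")
  }
  list(similarity_mean = mean(sims, na.rm = TRUE), per_replicate = sims,
       n_failed = n_failed)
}

#' Gold-standard gene ranking metrics
#'
#' Given a differential-expression ranking and a set of genes independently
#' known to change along the process, reports the mean rank of the gold genes
#' and, for each cutoff R in `top_grid`, how many gold genes fall in the top R.
#'
#' @param result a [detect_differential()] result.
#' @param gold character vector of gold-standard gene ids.
#' @param top_grid cutoffs R (default `seq(200, 2000, by = 200)`); cutoffs
#'   beyond the number of tested genes are truncated.
#' @return list with `mean_rank`, `top_counts` (named by R), `n_gold_tested`.
#' @export
gold_gene_metrics <- function(result, gold,
                              top_grid = seq(200L, 2000L, by = 200L)) {
  stopifnot(inherits(result, "de_result"))
  found <- intersect(gold, result$gene_id)
  if (!length(found)) {
    stop("no gold-standard gene was tested; missing: ",
         paste(utils::head(gold, 10), collapse = ", "))
  }
  ranks <- result$rank[match(found, result$gene_id)]
  grid <- pmin(as.integer(top_grid), nrow(result))
  counts <- vapply(grid, function(r) sum(ranks <= r), integer(1))
  list(mean_rank = mean(ranks),
       top_counts = stats::setNames(counts, top_grid),
       n_gold_tested = length(found))
}
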