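#' Simulate a single-cell trajectory with known latent pseudotime
#'
#' Generates a genes x cells matrix on a log-expression scale around a latent
#' trajectory. Each cell carries a latent position t ~ Uniform(0, 1). Trend
#' genes follow a shape in t (linear, sigmoid or transient bump, assigned
#' round-robin, half of them decreasing) with amplitude drawn from
#' Uniform(2, 5) over a Uniform(0.5, 2) baseline; flat genes sit at a
#' Uniform(0.5, 3) baseline. Gaussian noise (SD `noise_sd`) is added, values
#' are clamped at 0, and drop-out zeroes each entry independently with
#' probability `dropout_rate * exp(-value)`, so highly expressed entries are
#' rarely lost. Collection-time labels are the equal-width bin index of t into
#' `n_timepoints` bins; because noise crosses bin edges, the labels only
#' roughly reflect the true order, as in a real time-course design. With
#' `branch = TRUE`, cells past `branch_point` split evenly into two lineages
#' and half of the trend genes mirror their trajectory in the second lineage.
#'
#' @param n_cells number of cells (default 300).
#' @param n_genes number of genes (default 500).
#' @param n_trend_genes number of genes carrying a trend (default 100).
#' @param branch simulate a bifurcation (default `FALSE`).
#' @param branch_point latent position of the bifurcation, in (0, 1).
#' @param noise_sd Gaussian noise SD on the log scale (default 1).
#' @param dropout_rate baseline drop-out probability in [0, 1) (default 0.2).
#' @param n_timepoints number of collection time points V (default 4).
#' @param trend_shapes shapes cycled over the trend genes.
#' @param seed integer seed.
#' @return list with `matrix` (an [expression_matrix()] with collection-time
#'   labels), `truth` (data.frame: `cell_id`, `t`, `branch`, `time_bin`) and
#'   `trend_genes` (character vector).
#' @export
simulate_trajectory <- function(n_cells = 300, n_genes = 500,
                                n_trend_genes = 100, branch = FALSE,
                                branch_point = 0.5, noise_sd = 1,
                                dropout_rate = 0.2, n_timepoints = 4,
                                trend_shapes = c("linear", "sigmoid",
                                                 "transient"),
                                seed = 1L) {
  stopifnot(n_trend_genes <= n_genes, branch_point > 0, branch_point < 1,
            dropout_rate >= 0, dropout_rate < 1, noise_sd >= 0,
            n_timepoints >= 1)
  trend_shapes <- match.arg(trend_shapes, several.ok = TRUE)
  set.seed(seed)
  t <- stats::runif(n_cells)
  cell_ids <- sprintf("cell_%04d", seq_len(n_cells))
  gene_ids <- sprintf("gene_%04d", seq_len(n_genes))
  lineage <- rep(1L, n_cells)
  if (branch) {
    past <- which(t > branch_point)
    lineage[past] <- 1L + (seq_along(past) %% 2L)
  }
  shape01 <- function(shape, t) {
    switch(shape,
           linear = t,
           sigmoid = 1 / (1 + exp(-10 * (t - 0.5))),
           transient = exp(-(t - 0.5)^2 / (2 * 0.15^2)))
  }
  vals <- matrix(0, n_genes, n_cells)
  trend_idx <- seq_len(n_trend_genes)
  shapes <- rep_len(trend_shapes, n_trend_genes)
  amp <- stats::runif(n_trend_genes, 2, 5)
  base_t <- stats::runif(n_trend_genes, 0.5, 2)
  decreasing <- seq_len(n_trend_genes) %% 2L == 0L
  # with a branch, trend genes cycle through: shared trend, lineage-1-specific
  # activation, lineage-2-specific activation
  group <- if (branch) seq_len(n_trend_genes) %% 3L else rep(-1L, n_trend_genes)
  for (g in trend_idx) {
    if (group[g] %in% c(1L, 2L)) {
      target <- if (group[g] == 1L) 1L else 2L
      # silent before the branch point, then ramps up only in its lineage
      ramp <- pmax(0, (t - branch_point) / (1 - branch_point))
      s <- ifelse(t > branch_point & lineage == target,
                  shape01(shapes[g], ramp), 0)
    } else {
      s <- shape01(shapes[g], t)
      if (decreasing[g]) s <- 1 - s
    }
    vals[g, ] <- base_t[g] + amp[g] * s
  }
  if (n_trend_genes < n_genes) {
    flat <- seq.int(n_trend_genes + 1L, n_genes)
    vals[flat, ] <- stats::runif(length(flat), 0.5, 3)
  }
  if (noise_sd > 0) {
    vals <- vals + matrix(stats::rnorm(n_genes * n_cells, sd = noise_sd),
                          n_genes, n_cells)
  }
  vals <- pmax(vals, 0)
  if (dropout_rate > 0) {
    p_drop <- dropout_rate * exp(-vals)
    vals[matrix(stats::runif(n_genes * n_cells), n_genes, n_cells) < p_drop] <- 0
  }
  time_bin <- pmin(floor(t * n_timepoints) + 1L, n_timepoints)
  m <- expression_matrix(vals, gene_ids = gene_ids, cell_ids = cell_ids,
                         collection_time = time_bin)
  list(matrix = m,
       truth = data.frame(cell_id = cell_ids, t = t, branch = lineage,
                          time_bin = time_bin, stringsAsFactors = FALSE),
       trend_genes = gene_ids[trend_idx])
}

#' Simulate a two-segment scree vector
#'
#' Produces a continuous piecewise-linear, non-increasing vector with a slope
#' change at `breakpoint`, plus optional Gaussian noise (the result is
#' re-sorted non-increasing so it remains a valid scree).
#'
#' @param n_points length of the vector.
#' @param breakpoint index of the slope change, in [2, n_points - 1].
#' @param slopes length-2 numeric, both <= 0: slopes before and after the
#'   breakpoint.
#' @param noise_sd Gaussian noise SD (default 0).
#' @param seed integer seed.
#' @param intercept value at i = 1 (default 10).
#' @return numeric non-increasing vector of length `n_points`.
#' @export
simulate_scree <- function(n_points, breakpoint, slopes, noise_sd = 0,
                           seed = 1L, intercept = 10) {
  stopifnot(length(slopes) == 2, n_points >= 4)
  if (any(slopes > 0)) stop("scree slopes must be <= 0")
  if (breakpoint < 2 || breakpoint > n_points - 1) {
    stop("breakpoint must lie in [2, n_points - 1]")
  }
  i <- seq_len(n_points)
  v <- ifelse(i <= breakpoint,
              intercept + slopes[1] * (i - 1),
              intercept + slopes[1] * (breakpoint - 1) +
                slopes[2] * (i - breakpoint))
  if (noise_sd > 0) {
    set.seed(seed)
    v <- v + stats::rnorm(n_points, sd = noise_sd)
    v <- sort(v, decreasing = TRUE)
  }
  v
}
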