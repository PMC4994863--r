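#' Likelihood-ratio test of one gene's expression against pseudotime
#'
#' Fits a generalized additive model with a fixed-flexibility smooth of
#' pseudotime (effective degrees of freedom = `edf`, default 3, i.e. an
#' intercept plus `edf - 1` smooth parameters) under a Gaussian likelihood,
#' compares it by likelihood ratio to a constant-expression null model, and
#' returns the upper-tail chi-square p-value. The reference df is taken from
#' the fitted model's actual parameter count minus one, not hard-coded.
#'
#' P-values are conditional on the ordering: they do not account for the fact
#' that pseudotime was estimated from the same data.
#'
#' @param expr numeric expression vector over the ordered cells (length >= 10).
#' @param pseudotime integer ranks, a permutation of 1..length(expr).
#' @param edf effective degrees of freedom of the smooth fit (default 3).
#' @return list with `lr_stat`, `df`, `pvalue`, `smooth_loglik`,
#'   `null_loglik`.
#' @export
test_gene_along_pseudotime <- function(expr, pseudotime, edf = 3) {
  n <- length(expr)
  if (n < 10) stop("need at least 10 cells")
  if (length(pseudotime) != n || !all(sort(pseudotime) == seq_len(n))) {
    stop("pseudotime must be a permutation of 1..", n)
  }
  if (stats::var(expr) == 0) {
    return(list(lr_stat = 0, df = edf - 1, pvalue = 1,
                smooth_loglik = NA_real_, null_loglik = NA_real_))
  }
  pt <- as.numeric(pseudotime)
  fit1 <- mgcv::gam(expr ~ s(pt, k = edf, fx = TRUE))
  fit0 <- mgcv::gam(expr ~ 1)
  l1 <- as.numeric(stats::logLik(fit1))
  l0 <- as.numeric(stats::logLik(fit0))
  lr <- max(0, 2 * (l1 - l0))
  df <- length(stats::coef(fit1)) - 1
  p <- stats::pchisq(lr, df = df, lower.tail = FALSE)
  list(lr_stat = lr, df = df, pvalue = max(p, .Machine$double.xmin),
       smooth_loglik = l1, null_loglik = l0)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values, clipped to [0, 1] and monotone non-decreasing in
#' p-value rank.
#'
#' @param pvalues numeric vector of p-values in [0, 1]; no missing values.
#' @return vector of adjusted values (FDR), same order as the input.
#' @export
fdr_adjust <- function(pvalues) {
  if (anyNA(pvalues)) stop("missing or NaN p-value")
  if (any(pvalues < 0 | pvalues > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Detect genes differentially expressed along an ordered path
#'
#' Applies [test_gene_along_pseudotime()] to every gene over the path's cells,
#' adjusts p-values by Benjamini-Hochberg, and ranks genes by ascending FDR
#' (ties by ascending p-value, then input gene order). Genes with
#' `fdr < threshold` are flagged differential.
#'
#' @param m an [expression_matrix()] containing all path cells.
#' @param path an `ordered_path`.
#' @param edf smooth flexibility, see [test_gene_along_pseudotime()].
#' @param threshold FDR cutoff for the differential flag (default 0.05).
#' @return data.frame of class `de_result` with columns `gene_id`, `lr_stat`,
#'   `df`, `pvalue`, `fdr`, `rank`, `differential`, ordered as the input
#'   genes; `edf` and `threshold` are stored as attributes.
#' @export
detect_differential <- function(m, path, edf = 3, threshold = 0.05) {
  stopifnot(inherits(m, "expression_matrix"), inherits(path, "ordered_path"))
  miss <- setdiff(path$cell_order, m$cell_ids)
  if (length(miss)) stop("path cell(s) missing from matrix: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  sub <- m$values[, path$cell_order, drop = FALSE]
  pt <- seq_along(path$cell_order)
  tests <- lapply(seq_len(nrow(sub)), function(i) {
    test_gene_along_pseudotime(sub[i, ], pt, edf = edf)
  })
  res <- data.frame(
    gene_id = m$gene_ids,
    lr_stat = vapply(tests, `[[`, numeric(1), "lr_stat"),
    df = vapply(tests, `[[`, numeric(1), "df"),
    pvalue = vapply(tests, `[[`, numeric(1), "pvalue"),
    stringsAsFactors = FALSE)
  res$fdr <- fdr_adjust(res$pvalue)
  ord <- order(res$fdr, res$pvalue, seq_len(nrow(res)))
  res$rank <- integer(nrow(res))
  res$rank[ord] <- seq_len(nrow(res))
  res$differential <- res$fdr < threshold
  attr(res, "edf") <- edf
  attr(res, "threshold") <- threshold
  class(res) <- c("de_result", "data.frame")
  res
}

#' Write a differential-expression table as TSV
#'
#' @param res a [detect_differential()] result.
#' @param path output file.
#' @export
write_de_table <- function(res, path) {
  utils::write.table(as.data.frame(res)[
    , c("gene_id", "lr_stat", "pvalue", "fdr", "rank", "differential")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
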