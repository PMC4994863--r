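#' Assemble a pipeline run configuration
#'
#' Collects every knob of the end-to-end run into one record that is
#' serialized alongside the outputs, so a run can be reproduced exactly.
#'
#' @param log_transform apply log(y + pseudocount) before analysis.
#' @param pseudocount,log_base transform parameters.
#' @param gene_cluster_fraction gene-module count as a fraction of retained
#'   genes (default 0.05).
#' @param max_pcs_for_fit,k_override scree-fit controls, see
#'   [reduce_dimension()].
#' @param cluster_method,n_clusters,candidate_range cell-clustering controls,
#'   see [cluster_cells()].
#' @param origin origin cluster id for path enumeration (`NULL` = the
#'   lower-id end of the main path).
#' @param marker,marker_direction orient the main path by this gene's trend.
#' @param trim named numeric vector of marker-trimming thresholds: a cell is
#'   removed before ordering only if its expression exceeds the threshold for
#'   every listed gene (conjunction).
#' @param manual_path user-specified cluster sequence, validated against the
#'   tree and used verbatim.
#' @param edf,fdr_threshold differential-expression controls.
#' @param seed global seed; per-stage seeds are derived as seed + fixed small
#'   offsets (clustering +1, evaluation +2).
#' @return a list of class `run_config`.
#' @export
run_config <- function(log_transform = FALSE, pseudocount = 1, log_base = 2,
                       gene_cluster_fraction = 0.05, max_pcs_for_fit = 20,
                       k_override = NULL,
                       cluster_method = c("gmm", "kmeans", "none"),
                       n_clusters = NULL, candidate_range = 2:9,
                       origin = NULL, marker = NULL,
                       marker_direction = "increasing", trim = NULL,
                       manual_path = NULL, edf = 3, fdr_threshold = 0.05,
                       seed = 1L) {
  structure(list(log_transform = log_transform, pseudocount = pseudocount,
                 log_base = log_base,
                 gene_cluster_fraction = gene_cluster_fraction,
                 max_pcs_for_fit = max_pcs_for_fit, k_override = k_override,
                 cluster_method = match.arg(cluster_method),
                 n_clusters = n_clusters, candidate_range = candidate_range,
                 origin = origin, marker = marker,
                 marker_direction = marker_direction, trim = trim,
                 manual_path = manual_path, edf = edf,
                 fdr_threshold = fdr_threshold, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full ordering pipeline on an expression matrix
#'
#' Executes transform, zero-gene filtering, gene clustering and averaging,
#' PCA with scree-based component selection, cell clustering, spanning-tree
#' construction, path enumeration, cell projection/ordering, differential
#' expression along the main path, and (when collection-time labels are
#' present) POS evaluation.
#'
#' @param m an [expression_matrix()].
#' @param cfg a [run_config()].
#' @param de run the differential-expression stage (default `TRUE`; skipping
#'   it is useful inside perturbation loops).
#' @return a list of class `pipeline_result` with `reduced`, `model`, `tree`,
#'   `paths` (list of `ordered_path`, main path first), `main_path`, `de`
#'   (or `NULL`), `pos` (or `NULL`), `config`.
#' @export
run_pipeline <- function(m, cfg = run_config(), de = TRUE) {
  stopifnot(inherits(m, "expression_matrix"), inherits(cfg, "run_config"))
  if (cfg$log_transform) {
    m <- log_transform(m, pseudocount = cfg$pseudocount, base = cfg$log_base)
  }
  if (!is.null(cfg$trim)) {
    over <- rep(TRUE, length(m$cell_ids))
    for (g in names(cfg$trim)) {
      if (!g %in% m$gene_ids) stop("trimming gene not found: ", g)
      over <- over & m$values[g, ] > cfg$trim[[g]]
    }
    if (all(over)) stop("marker trimming removed every cell")
    m <- subset_cells(m, which(!over))
  }
  red <- preprocess(m, fraction = cfg$gene_cluster_fraction,
                    max_pcs_for_fit = cfg$max_pcs_for_fit,
                    k_override = cfg$k_override)
  model <- cluster_cells(red, method = cfg$cluster_method,
                         n_clusters = cfg$n_clusters,
                         candidate_range = cfg$candidate_range,
                         seed = cfg$seed + 1L)
  if (model$n_clusters == 1) {
    main <- order_single_cluster(red)
    paths <- list(main)
    tree <- NULL
  } else {
    tree <- build_mst(model)
    if (!is.null(cfg$manual_path)) {
      main_seq <- validate_manual_path(tree, cfg$manual_path)
    } else {
      main_seq <- find_main_path(tree)
      if (!is.null(cfg$origin)) {
        if (!cfg$origin %in% c(main_seq[1], main_seq[length(main_seq)])) {
          stop("origin must be an end of the main path (",
               main_seq[1], " or ", main_seq[length(main_seq)], ")")
        }
        if (cfg$origin == main_seq[length(main_seq)]) main_seq <- rev(main_seq)
      }
      if (!is.null(cfg$marker)) {
        mf <- filter_zero_genes(m)
        if (!cfg$marker %in% mf$gene_ids) {
          stop("marker gene not found: ", cfg$marker)
        }
        mm <- vapply(main_seq, function(cl) {
          mean(mf$values[cfg$marker, names(model$labels)[model$labels == cl]])
        }, numeric(1))
        names(mm) <- as.character(main_seq)
        main_seq <- orient_path(main_seq, mm, cfg$marker_direction)
      }
    }
    main <- order_cells_along_path(main_seq, model, red, is_main = TRUE)
    branch_seqs <- enumerate_paths(tree, origin = main_seq[1])
    branch_seqs <- Filter(function(p) !identical(p, main_seq), branch_seqs)
    paths <- c(list(main), lapply(branch_seqs, function(p) {
      order_cells_along_path(p, model, red, is_main = FALSE)
    }))
  }
  de_res <- if (de) {
    detect_differential(m, main, edf = cfg$edf,
                        threshold = cfg$fdr_threshold)
  }
  pos <- if (!is.null(m$collection_time)) {
    pos_score(main$cell_order, m$collection_time)
  }
  structure(list(reduced = red, model = model, tree = tree, paths = paths,
                 main_path = main, de = de_res, pos = pos, config = cfg),
            class = "pipeline_result")
}

#' Run the pipeline and write all artifacts to a directory
#'
#' @param m an [expression_matrix()].
#' @param outdir output directory (created if missing).
#' @param cfg a [run_config()].
#' @return the [run_pipeline()] result, invisibly. Writes `ordering_<i>.tsv`
#'   per path, `tree.json`, `de.tsv`, `evaluation.json` (when labels exist)
#'   and `manifest.json` (package version, seed, config).
#' @export
run_pipeline_dir <- function(m, outdir, cfg = run_config()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  res <- run_pipeline(m, cfg)
  for (i in seq_along(res$paths)) {
    write_ordering(res$paths[[i]], file.path(outdir,
                                             sprintf("ordering_%d.tsv", i)))
  }
  if (!is.null(res$tree)) {
    write_tree_json(res$tree, file.path(outdir, "tree.json"),
                    main_path = res$main_path$cluster_sequence)
  }
  if (!is.null(res$de)) write_de_table(res$de, file.path(outdir, "de.tsv"))
  if (!is.null(res$pos)) {
    jsonlite::write_json(list(pos = res$pos),
                         file.path(outdir, "evaluation.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  manifest <- list(
    package = "pseudopath",
    version = as.character(utils::packageVersion("pseudopath")),
    seed = cfg$seed,
    config = cfg[!vapply(cfg, is.null, logical(1))])
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}
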