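#' Build the minimum spanning tree over cluster centers
#'
#' Connects all cluster centers by the spanning tree of smallest total
#' Euclidean edge length. Prim's algorithm is grown from the lowest-indexed
#' node; equal-length edges are broken by the lexicographically smallest
#' (min id, max id) pair, so the tree is deterministic even with tied or
#' duplicate centers.
#'
#' @param model a [cluster_cells()] result with at least 2 clusters.
#' @return a list of class `cluster_tree` with `nodes` (data.frame: `id`,
#'   `n_cells`), `centers`, `edges` (data.frame: `from`, `to`, `length`,
#'   with `from < to`) and `total_length`.
#' @export
build_mst <- function(model) {
  stopifnot(inherits(model, "cell_cluster_model"))
  centers <- model$centers
  n <- nrow(centers)
  if (n < 2) {
    stop("single cluster: no tree to build; order cells along PC 1 instead ",
         "(see order_single_cluster)")
  }
  d <- as.matrix(stats::dist(centers))
  in_tree <- rep(FALSE, n)
  in_tree[1] <- TRUE
  edges <- data.frame(from = integer(n - 1), to = integer(n - 1),
                      length = numeric(n - 1))
  for (step in seq_len(n - 1)) {
    best <- NULL
    for (i in which(in_tree)) {
      for (j in which(!in_tree)) {
        cand <- c(min(i, j), max(i, j), d[i, j])
        if (is.null(best) || cand[3] < best[3] - 1e-12 ||
            (abs(cand[3] - best[3]) <= 1e-12 &&
             (cand[1] < best[1] || (cand[1] == best[1] && cand[2] < best[2])))) {
          best <- cand
        }
      }
    }
    edges[step, ] <- best
    in_tree[best[1]] <- TRUE
    in_tree[best[2]] <- TRUE
  }
  edges$from <- as.integer(edges$from)
  edges$to <- as.integer(edges$to)
  edges <- edges[order(edges$from, edges$to), ]
  rownames(edges) <- NULL
  counts <- as.integer(model$cells_per_cluster[as.character(seq_len(n))])
  structure(list(nodes = data.frame(id = seq_len(n), n_cells = counts),
                 centers = centers, edges = edges,
                 total_length = sum(edges$length)),
            class = "cluster_tree")
}

# adjacency list of a cluster_tree
tree_adjacency <- function(tree) {
  n <- nrow(tree$nodes)
  adj <- vector("list", n)
  for (e in seq_len(nrow(tree$edges))) {
    a <- tree$edges$from[e]; b <- tree$edges$to[e]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# unique simple path between two nodes of a tree (DFS)
tree_path <- function(adj, from, to) {
  from <- as.integer(from); to <- as.integer(to)
  stack <- list(from)
  parent <- rep(NA_integer_, length(adj))
  seen <- rep(FALSE, length(adj))
  seen[from] <- TRUE
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (v == to) break
    for (w in adj[[v]]) {
      if (!seen[w]) {
        seen[w] <- TRUE
        parent[w] <- v
        stack[[length(stack) + 1]] <- w
      }
    }
  }
  path <- to
  while (!is.na(parent[path[1]])) path <- c(parent[path[1]], path)
  path
}

# orient a path canonically: smaller end first; for palindromic ties compare
# the full sequences lexicographically
canonical_orientation <- function(path) {
  rev_path <- rev(path)
  for (i in seq_along(path)) {
    if (path[i] < rev_path[i]) return(path)
    if (path[i] > rev_path[i]) return(rev_path)
  }
  path
}

#' Find the main path of a cluster tree
#'
#' The main path is the leaf-to-leaf path with the largest number of clusters;
#' ties are broken by the largest total number of member cells, then by the
#' lexicographically smallest cluster-id sequence after canonical orientation.
#'
#' @param tree a [build_mst()] result.
#' @return integer vector of cluster ids along the main path.
#' @export
find_main_path <- function(tree) {
  stopifnot(inherits(tree, "cluster_tree"))
  adj <- tree_adjacency(tree)
  deg <- lengths(adj)
  leaves <- which(deg <= 1)
  if (length(leaves) < 2) stop("tree has fewer than 2 leaves")
  best <- NULL; best_cells <- -1
  for (a in leaves) for (b in leaves) {
    if (a >= b) next
    p <- canonical_orientation(tree_path(adj, a, b))
    cells <- sum(tree$nodes$n_cells[p])
    if (is.null(best) ||
        length(p) > length(best) ||
        (length(p) == length(best) && cells > best_cells) ||
        (length(p) == length(best) && cells == best_cells &&
         path_less(p, best))) {
      best <- p; best_cells <- cells
    }
  }
  best
}

# lexicographic comparison of two equal-length integer sequences
path_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

#' Enumerate all branching paths from an origin
#'
#' Returns every simple path from the origin cluster to each leaf of the tree
#' (excluding the trivial path when the origin is itself that leaf). When the
#' origin is one end of the main path, the first of these paths is the main
#' path itself and the rest are branch paths.
#'
#' @param tree a [build_mst()] result.
#' @param origin cluster id to start from.
#' @return list of integer vectors (cluster-id paths), ordered by their end
#'   leaf id.
#' @export
enumerate_paths <- function(tree, origin) {
  stopifnot(inherits(tree, "cluster_tree"))
  if (!origin %in% tree$nodes$id) stop("unknown origin cluster: ", origin)
  adj <- tree_adjacency(tree)
  leaves <- which(lengths(adj) <= 1)
  leaves <- setdiff(leaves, origin)
  lapply(leaves, function(l) tree_path(adj, origin, l))
}

#' Orient a cluster path by marker-gene expression
#'
#' Flips the path, if needed, so that the least-squares linear trend of the
#' marker gene's per-cluster mean expression along the path has the requested
#' sign. With an exactly flat trend the input orientation is kept and a
#' warning is raised.
#'
#' @param path integer vector of cluster ids.
#' @param marker_means numeric vector of the marker gene's mean expression
#'   per cluster, named by cluster id (or positional, matching `path`).
#' @param direction `"increasing"` or `"decreasing"`.
#' @return the (possibly reversed) path.
#' @export
orient_path <- function(path, marker_means,
                        direction = c("increasing", "decreasing")) {
  direction <- match.arg(direction)
  mm <- if (!is.null(names(marker_means))) {
    miss <- setdiff(as.character(path), names(marker_means))
    if (length(miss)) stop("no marker mean for cluster(s): ",
                           paste(miss, collapse = ", "))
    marker_means[as.character(path)]
  } else {
    stopifnot(length(marker_means) == length(path))
    marker_means
  }
  slope <- stats::cov(seq_along(path), mm)
  if (slope == 0) {
    warning("flat marker trend along path; keeping input orientation")
    return(path)
  }
  want <- if (direction == "increasing") 1 else -1
  if (sign(slope) == want) path else rev(path)
}

#' Project cells onto a cluster path and order them
#'
#' Implements the cell-level ordering along an ordered cluster path
#' C_1, ..., C_M. Cells of the first cluster are projected onto the edge
#' (C_1, C_2) and cells of the last onto (C_{M-1}, C_M); cells of an interior
#' cluster C_m go to the edge toward whichever neighboring center (C_{m-1} or
#' C_{m+1}) is nearer in Euclidean distance (ties to the earlier edge). The
#' projection of a cell with coordinates E onto the edge from center_i to
#' center_j is the inner product t(v) %*% E / ||v|| with v = center_j -
#' center_i. Cells are then sorted by (cluster position on the path, edge
#' order within the cluster, projection value, stable input index), and
#' pseudotime is the resulting rank 1..N.
#'
#' @param path integer vector of >= 2 cluster ids, in order.
#' @param model a [cluster_cells()] result.
#' @param r the [reduce_dimension()] result the model was fitted on.
#' @param is_main flag stored on the result (default `TRUE`).
#' @return a list of class `ordered_path` with `cluster_sequence`,
#'   `cell_order` (cell ids), `pseudotime` (named integer ranks),
#'   `edge_assignment` (data.frame: `cell_id`, `cluster`, `edge_from`,
#'   `edge_to`, `projection`) and `is_main`.
#' @export
order_cells_along_path <- function(path, model, r, is_main = TRUE) {
  stopifnot(inherits(model, "cell_cluster_model"),
            inherits(r, "reduced_matrix"))
  m_len <- length(path)
  if (m_len < 2) stop("path must contain at least 2 clusters")
  coords <- r$coords
  centers <- model$centers
  rows <- list()
  for (pos in seq_len(m_len)) {
    cl <- path[pos]
    cells <- names(model$labels)[model$labels == cl]
    if (!length(cells)) stop("cluster ", cl, " on the path has no cells")
    if (pos == 1) {
      edge_pos <- rep(1L, length(cells))          # edge (C_1, C_2)
    } else if (pos == m_len) {
      edge_pos <- rep(m_len - 1L, length(cells))  # edge (C_{M-1}, C_M)
    } else {
      d_prev <- sqrt(colSums((t(coords[cells, , drop = FALSE]) -
                                centers[path[pos - 1], ])^2))
      d_next <- sqrt(colSums((t(coords[cells, , drop = FALSE]) -
                                centers[path[pos + 1], ])^2))
      edge_pos <- ifelse(d_prev <= d_next, pos - 1L, pos)
    }
    v_from <- path[edge_pos]; v_to <- path[edge_pos + 1L]
    proj <- vapply(seq_along(cells), function(i) {
      v <- centers[v_to[i], ] - centers[v_from[i], ]
      sum(v * coords[cells[i], ]) / sqrt(sum(v^2))
    }, numeric(1))
    rows[[pos]] <- data.frame(cell_id = cells, cluster = cl,
                              cluster_pos = pos, edge_pos = edge_pos,
                              edge_from = v_from, edge_to = v_to,
                              projection = proj, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  tab$input_idx <- match(tab$cell_id, rownames(coords))
  ord <- order(tab$cluster_pos, tab$edge_pos, tab$projection, tab$input_idx)
  tab <- tab[ord, ]
  rownames(tab) <- NULL
  structure(list(cluster_sequence = path,
                 cell_order = tab$cell_id,
                 pseudotime = stats::setNames(seq_len(nrow(tab)), tab$cell_id),
                 edge_assignment = tab[, c("cell_id", "cluster", "edge_from",
                                           "edge_to", "projection")],
                 is_main = is_main),
            class = "ordered_path")
}

#' @export
print.ordered_path <- function(x, ...) {
  cat("ordered_path: ", length(x$cell_order), " cells along clusters ",
      paste(x$cluster_sequence, collapse = "-"),
      if (isTRUE(x$is_main)) " (main path)", "\n", sep = "")
  invisible(x)
}

#' Fallback ordering when clustering yields a single cluster
#'
#' Orders all cells by their first principal component. Used when the mixture
#' model collapses to one component, where no cluster-level tree exists.
#'
#' @param r a [reduce_dimension()] result.
#' @return an `ordered_path` covering all cells (cluster_sequence `1`).
#' @export
order_single_cluster <- function(r) {
  stopifnot(inherits(r, "reduced_matrix"))
  warning("single cluster: ordering cells by their PC 1 coordinate")
  pc1 <- r$coords[, 1]
  idx <- order(pc1, seq_along(pc1))
  cells <- rownames(r$coords)[idx]
  structure(list(cluster_sequence = 1L, cell_order = cells,
                 pseudotime = stats::setNames(seq_along(cells), cells),
                 edge_assignment = data.frame(
                   cell_id = cells, cluster = 1L, edge_from = NA_integer_,
                   edge_to = NA_integer_, projection = pc1[idx]),
                 is_main = TRUE),
            class = "ordered_path")
}

#' Order cells directly by a single marker gene
#'
#' Baseline ordering that bypasses trajectory reconstruction entirely: cells
#' are sorted by the expression of one marker gene (ascending for
#' `"increasing"`), with ties kept in input order, and pseudotime is the rank.
#'
#' @param m an [expression_matrix()].
#' @param gene gene id to sort by.
#' @param direction `"increasing"` or `"decreasing"`.
#' @return an `ordered_path` (cluster_sequence is `NA`; no edge projections).
#' @export
marker_only_ordering <- function(m, gene,
                                 direction = c("increasing", "decreasing")) {
  stopifnot(inherits(m, "expression_matrix"))
  direction <- match.arg(direction)
  if (!gene %in% m$gene_ids) stop("unknown gene: ", gene)
  expr <- m$values[gene, ]
  key <- if (direction == "increasing") expr else -expr
  idx <- order(key, seq_along(expr))
  cells <- m$cell_ids[idx]
  structure(list(cluster_sequence = NA_integer_, cell_order = cells,
                 pseudotime = stats::setNames(seq_along(cells), cells),
                 edge_assignment = data.frame(
                   cell_id = cells, cluster = NA_integer_,
                   edge_from = NA_integer_, edge_to = NA_integer_,
                   projection = expr[idx]),
                 is_main = TRUE),
            class = "ordered_path")
}

#' Validate a manually specified cluster path
#'
#' Accepts a user-supplied cluster ordering verbatim after checking that it is
#' a simple path in the tree (consecutive clusters joined by tree edges, no
#' repeats).
#'
#' @param tree a [build_mst()] result.
#' @param path integer vector of cluster ids.
#' @return the path, invisibly, if valid; otherwise an error.
#' @export
validate_manual_path <- function(tree, path) {
  stopifnot(inherits(tree, "cluster_tree"))
  if (anyDuplicated(path)) stop("manual path repeats a cluster")
  if (!all(path %in% tree$nodes$id)) stop("manual path names unknown clusters")
  key <- paste(pmin(tree$edges$from, tree$edges$to),
               pmax(tree$edges$from, tree$edges$to))
  for (i in seq_len(length(path) - 1)) {
    k <- paste(min(path[i], path[i + 1]), max(path[i], path[i + 1]))
    if (!k %in% key) {
      stop("clusters ", path[i], " and ", path[i + 1],
           " are not joined by a tree edge")
    }
  }
  invisible(path)
}

#' Serialize a cluster tree to JSON
#'
#' @param tree a [build_mst()] result.
#' @param path output file.
#' @param main_path optional main-path cluster sequence to record.
#' @export
write_tree_json <- function(tree, path, main_path = NULL) {
  stopifnot(inherits(tree, "cluster_tree"))
  obj <- list(
    nodes = lapply(seq_len(nrow(tree$nodes)), function(i) {
      list(id = tree$nodes$id[i], center = unname(tree$centers[i, ]),
           n_cells = tree$nodes$n_cells[i])
    }),
    edges = lapply(seq_len(nrow(tree$edges)), function(i) {
      list(a = tree$edges$from[i], b = tree$edges$to[i],
           length = tree$edges$length[i])
    }),
    total_length = tree$total_length)
  if (!is.null(main_path)) obj$main_path <- as.integer(main_path)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write an ordered path as TSV
#'
#' Columns: `cell_id`, `cluster`, `edge`, `projection`, `pseudotime`.
#'
#' @param p an `ordered_path`.
#' @param path output file.
#' @export
write_ordering <- function(p, path) {
  stopifnot(inherits(p, "ordered_path"))
  ea <- p$edge_assignment
  tab <- data.frame(cell_id = ea$cell_id, cluster = ea$cluster,
                    edge = paste0(ea$edge_from, "-", ea$edge_to),
                    projection = ea$projection,
                    pseudotime = p$pseudotime[ea$cell_id])
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
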