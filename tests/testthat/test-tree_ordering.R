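# minimal cell_cluster_model from explicit centers and per-cluster cell counts
make_model <- function(centers, counts = rep(1L, nrow(centers)), coords = NULL,
                       labels = NULL) {
  n_cl <- nrow(centers)
  rownames(centers) <- as.character(seq_len(n_cl))
  if (is.null(labels)) labels <- rep(seq_len(n_cl), counts)
  if (is.null(coords)) {
    coords <- centers[labels, , drop = FALSE]
    rownames(coords) <- paste0("c", seq_along(labels))
  }
  names(labels) <- rownames(coords)
  structure(list(method = "kmeans", n_clusters = n_cl, labels = labels,
                 centers = centers,
                 cells_per_cluster = table(factor(labels,
                                                  levels = seq_len(n_cl)))),
            class = "cell_cluster_model")
}

as_reduced <- function(coords) {
  structure(list(coords = coords, cell_ids = rownames(coords)),
            class = "reduced_matrix")
}

test_that("collinear centers give a chain and two clusters a single edge", {
  model <- make_model(cbind(c(0, 1, 3), 0))
  tree <- build_mst(model)
  expect_equal(tree$edges[, c("from", "to")],
               data.frame(from = c(1, 2), to = c(2, 3)))
  expect_equal(tree$total_length, 3)
  t2 <- build_mst(make_model(cbind(c(0, 5), 0)))
  expect_equal(nrow(t2$edges), 1)
  expect_equal(t2$total_length, 5)
  expect_error(build_mst(make_model(cbind(0, 0))), "single cluster")
})

test_that("MST total length matches brute-force enumeration on random fixtures", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- sample(4:6, 1)
    centers <- matrix(rnorm(n * 3), n)
    tree <- build_mst(make_model(centers))
    expect_equal(nrow(tree$edges), n - 1)
    expect_equal(tree$total_length, brute_force_mst_length(centers),
                 tolerance = 1e-10)
    if (requireNamespace("igraph", quietly = TRUE)) {
      g <- igraph::graph_from_adjacency_matrix(
        as.matrix(dist(centers)), mode = "undirected", weighted = TRUE)
      expect_equal(tree$total_length,
                   sum(igraph::E(igraph::mst(g))$weight), tolerance = 1e-10)
    }
  }
})

test_that("duplicate centers are handled deterministically", {
  centers <- rbind(c(0, 0), c(0, 0), c(1, 0))
  t1 <- build_mst(make_model(centers))
  t2 <- build_mst(make_model(centers))
  expect_identical(t1$edges, t2$edges)
  expect_equal(t1$total_length, 1)
})

test_that("main path maximizes clusters then cells, with deterministic ties", {
  # chain: the full chain is the main path
  chain <- build_mst(make_model(cbind(1:4, 0)))
  expect_identical(find_main_path(chain), c(1L, 2L, 3L, 4L))
  # chain 1-2-3 with leaves 4 and 5 on node 3: 1-2-3-4 vs 1-2-3-5 tie at 4
  # clusters; the branch holding more cells wins
  centers <- rbind(c(0, 0), c(1, 0), c(2, 0), c(3, 1), c(3, -1))
  counts <- c(10L, 10L, 10L, 2L, 8L)
  tree <- build_mst(make_model(centers, counts))
  expect_identical(find_main_path(tree), c(1L, 2L, 3L, 5L))
  counts2 <- c(10L, 10L, 10L, 8L, 2L)
  tree2 <- build_mst(make_model(centers, counts2))
  expect_identical(find_main_path(tree2), c(1L, 2L, 3L, 4L))
  # star with 3 equal leaves and equal counts: lexicographically smallest wins
  star <- build_mst(make_model(rbind(c(0, 0), c(1, 0), c(-0.5, 0.866),
                                     c(-0.5, -0.866))))
  expect_identical(find_main_path(star), c(2L, 1L, 3L))
})

test_that("enumerate_paths lists every origin-to-leaf path", {
  centers <- rbind(c(0, 0), c(1, 0), c(2, 0), c(3, 1), c(3, -1))
  tree <- build_mst(make_model(centers, c(10L, 10L, 10L, 2L, 8L)))
  paths <- enumerate_paths(tree, origin = 1)
  expect_identical(paths, list(c(1L, 2L, 3L, 4L), c(1L, 2L, 3L, 5L)))
  chain <- build_mst(make_model(cbind(1:4, 0)))
  expect_identical(enumerate_paths(chain, origin = 2),
                   list(c(2L, 1L), c(2L, 3L, 4L)))
  expect_identical(enumerate_paths(chain, origin = 1),
                   list(c(1L, 2L, 3L, 4L)))
  expect_error(enumerate_paths(chain, origin = 9), "unknown origin")
})

test_that("orient_path follows the marker trend", {
  expect_identical(orient_path(1:3, c(0.1, 0.5, 2.0), "increasing"), 1:3)
  expect_identical(orient_path(1:3, c(2.0, 0.5, 0.1), "increasing"), 3:1)
  expect_identical(orient_path(1:3, c(0.1, 0.5, 2.0), "decreasing"), 3:1)
  expect_warning(out <- orient_path(1:3, c(1, 2, 1), "increasing"), "flat")
  expect_identical(out, 1:3)
  # named marker means are matched by cluster id
  expect_identical(orient_path(c(4L, 2L, 7L),
                               c(`7` = 3, `2` = 2, `4` = 1), "increasing"),
                   c(4L, 2L, 7L))
})

test_that("cells order by projection along the path (hand-computed toys)", {
  # two clusters on a line, centers 0 and 10
  coords <- cbind(c(1, 2, 8, 9))
  rownames(coords) <- paste0("c", 1:4)
  model <- make_model(cbind(c(0, 10)), coords = coords,
                      labels = c(1L, 1L, 2L, 2L))
  p <- order_cells_along_path(c(1L, 2L), model, as_reduced(coords))
  expect_identical(p$cell_order, c("c1", "c2", "c3", "c4"))
  expect_identical(unname(p$pseudotime), 1:4)
  # projections are inner products onto the unit edge vector
  expect_equal(p$edge_assignment$projection, c(1, 2, 8, 9))
  # 3 clusters at 0/10/20: C2 cell at 8 goes to edge (1,2); at 13 to (2,3)
  coords2 <- cbind(c(0.5, 8, 13, 19))
  rownames(coords2) <- paste0("c", 1:4)
  model2 <- make_model(cbind(c(0, 10, 20)), coords = coords2,
                       labels = c(1L, 2L, 2L, 3L))
  p2 <- order_cells_along_path(1:3, model2, as_reduced(coords2))
  ea <- p2$edge_assignment
  expect_identical(ea$edge_from[ea$cell_id == "c2"], 1L)
  expect_identical(ea$edge_to[ea$cell_id == "c2"], 2L)
  expect_identical(ea$edge_from[ea$cell_id == "c3"], 2L)
  expect_identical(p2$cell_order, c("c1", "c2", "c3", "c4"))
  # one cell per cluster: cell order equals cluster order
  model3 <- make_model(cbind(c(0, 5, 9)))
  coords3 <- model3$centers
  rownames(coords3) <- names(model3$labels)
  p3 <- order_cells_along_path(c(3L, 2L, 1L), model3, as_reduced(coords3))
  expect_identical(p3$cell_order, c("c3", "c2", "c1"))
})

test_that("pseudotime is a bijection and path reversal reverses the order", {
  set.seed(20)
  centers <- cbind(seq(0, 30, by = 10), 0)
  labels <- rep(1:4, each = 10)
  coords <- centers[labels, ] + matrix(rnorm(80, sd = 1.5), 40)
  rownames(coords) <- paste0("c", 1:40)
  model <- make_model(centers, coords = coords, labels = labels)
  p_fwd <- order_cells_along_path(1:4, model, as_reduced(coords))
  p_rev <- order_cells_along_path(4:1, model, as_reduced(coords))
  expect_identical(sort(unname(p_fwd$pseudotime)), 1:40)
  expect_identical(p_rev$cell_order, rev(p_fwd$cell_order))
})

test_that("1-D synthetic ordering recovers the latent positions", {
  set.seed(30)
  true_pos <- sort(runif(60, 0, 30))
  labels <- cut(true_pos, breaks = c(-1, 10, 20, 31), labels = FALSE)
  centers <- cbind(tapply(true_pos, labels, mean))
  coords <- cbind(true_pos) + matrix(rnorm(60, sd = 0.1), 60)
  rownames(coords) <- paste0("c", 1:60)
  model <- make_model(centers, coords = coords, labels = labels)
  # use empirical centers as the model does
  model$centers <- cbind(tapply(coords[, 1], labels, mean))
  rownames(model$centers) <- as.character(1:3)
  p <- order_cells_along_path(1:3, model, as_reduced(coords))
  expect_identical(p$cell_order, paste0("c", order(coords[, 1])))
})

test_that("marker-only ordering sorts by expression with stable ties", {
  m <- em(rbind(c(3, 1, 2), c(5, 5, 5)), genes = c("mk", "flat"))
  p <- marker_only_ordering(m, "mk")
  expect_identical(p$cell_order, c("c2", "c3", "c1"))
  expect_identical(unname(p$pseudotime[p$cell_order]), 1:3)
  # all-equal expression: input order preserved
  pf <- marker_only_ordering(m, "flat")
  expect_identical(pf$cell_order, c("c1", "c2", "c3"))
  # decreasing is the exact reverse on distinct values
  pd <- marker_only_ordering(m, "mk", "decreasing")
  expect_identical(pd$cell_order, rev(p$cell_order))
  expect_error(marker_only_ordering(m, "nope"), "unknown gene")
})

test_that("manual paths are validated against the tree", {
  tree <- build_mst(make_model(rbind(c(0, 0), c(1, 0), c(2, 0), c(3, 1),
                                     c(3, -1))))
  expect_invisible(validate_manual_path(tree, c(4L, 3L, 2L, 1L)))
  expect_error(validate_manual_path(tree, c(1L, 3L)), "not joined")
  expect_error(validate_manual_path(tree, c(1L, 2L, 1L)), "repeats")
  expect_error(validate_manual_path(tree, c(1L, 9L)), "unknown")
})

test_that("single-cluster fallback orders by PC 1 with a warning", {
  coords <- cbind(c(3, 1, 2), c(0, 0, 0))
  rownames(coords) <- paste0("c", 1:3)
  expect_warning(p <- order_single_cluster(as_reduced(coords)), "PC 1")
  expect_identical(p$cell_order, c("c2", "c3", "c1"))
})
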