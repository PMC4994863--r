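# Independent reference implementations used to validate the package's
# algorithms on small instances. Deliberately naive and written against the
# definitions, not the package code paths.

# quick expression_matrix from a plain matrix
em <- function(values, genes = NULL, cells = NULL, time = NULL) {
  g <- nrow(values); n <- ncol(values)
  expression_matrix(values,
                    gene_ids = if (is.null(genes)) paste0("g", seq_len(g)) else genes,
                    cell_ids = if (is.null(cells)) paste0("c", seq_len(n)) else cells,
                    collection_time = time)
}

# O(n^3) agglomerative complete-linkage clustering cut at k clusters
naive_complete_linkage <- function(x, k) {
  clusters <- as.list(seq_len(nrow(x)))
  d <- as.matrix(dist(x))
  while (length(clusters) > k) {
    best <- c(Inf, NA, NA)
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (a >= b) next
        link <- max(d[clusters[[a]], clusters[[b]]])
        if (link < best[1]) best <- c(link, a, b)
      }
    }
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  labels <- integer(nrow(x))
  for (i in seq_along(clusters)) labels[clusters[[i]]] <- i
  labels
}

# TRUE iff two label vectors define the same partition
same_partition <- function(a, b) {
  length(unique(a)) == length(unique(b)) &&
    all(tapply(b, a, function(v) length(unique(v))) == 1)
}

# total length of the minimum spanning tree by exhaustive enumeration of all
# (n-1)-edge subsets that connect the nodes
brute_force_mst_length <- function(centers) {
  n <- nrow(centers)
  d <- as.matrix(dist(centers))
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  best <- Inf
  for (sel in combn(nrow(pairs), n - 1, simplify = FALSE)) {
    e <- pairs[sel, , drop = FALSE]
    # connectivity check by label propagation
    comp <- seq_len(n)
    repeat {
      changed <- FALSE
      for (r in seq_len(nrow(e))) {
        m <- min(comp[e[r, ]])
        if (any(comp[e[r, ]] != m)) { comp[e[r, ]] <- m; changed <- TRUE }
      }
      if (!changed) break
    }
    if (length(unique(comp)) == 1) {
      best <- min(best, sum(d[e]))
    }
  }
  best
}

# POS of one ordering by the double-sum definition, given per-cell time
# indices tau (named) and a denominator
naive_pos_numerator <- function(ordering, tau) {
  t <- tau[ordering]
  n <- length(t)
  s <- 0
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) s <- s + (t[j] - t[i])
  unname(s)
}

# exhaustive POS over all permutations of <= 7 cells; returns the vector of
# normalized scores (numerator / max numerator)
exhaustive_pos <- function(tau) {
  cells <- names(tau)
  perms <- combinat_perms(cells)
  nums <- vapply(perms, naive_pos_numerator, numeric(1), tau = tau)
  nums / max(nums)
}

combinat_perms <- function(x) {
  if (length(x) == 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (p in combinat_perms(x[-i])) out[[length(out) + 1]] <- c(x[i], p)
  }
  out
}

# naive similarity: double loop over the union
naive_similarity <- function(pi1, pi2) {
  a <- union(pi1, pi2)
  n <- length(a)
  s <- 0
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    p1i <- match(a[i], pi1); p1j <- match(a[j], pi1)
    p2i <- match(a[i], pi2); p2j <- match(a[j], pi2)
    if (!anyNA(c(p1i, p1j, p2i, p2j)) &&
        sign(p1i - p1j) == sign(p2i - p2j)) s <- s + 1
  }
  2 * s / (n * (n - 1))
}

# constrained two-segment least squares via the broken-stick basis
# f(i) = a + b*i + c*max(i - k, 0); continuity at k holds by construction
broken_stick_sse <- function(x, y, k) {
  X <- cbind(1, x, pmax(x - k, 0))
  sum(lm.fit(X, y)$residuals^2)
}

broken_stick_breakpoint <- function(y, k_min = 2) {
  x <- seq_along(y)
  cand <- seq.int(k_min, length(y) - 1)
  sse <- vapply(cand, function(k) broken_stick_sse(x, y, k), numeric(1))
  cand[which(sse <= min(sse) + 1e-9 * max(sum((y - mean(y))^2), 1e-300))[1]]
}
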