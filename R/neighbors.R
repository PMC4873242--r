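#' Approximate / exact k-nearest-neighbor graph
#'
#' Builds the per-class neighbor graph the coarsening and refinement phases
#' operate on. Distances are Euclidean (matching the RBF kernel geometry on
#' standardized features). `mode = "exact"` computes true k-NN blockwise;
#' `mode = "approximate"` uses a small forest of random-projection trees
#' followed by one neighbor-of-neighbor refinement sweep, which reaches high
#' recall at a fraction of the all-pairs cost; `mode = "auto"` switches to the
#' approximate index above `exact_limit` points. Ties in distance are broken
#' by index.
#'
#' The returned graph stores the directed k-NN lists (`idx`, `dist`, sorted
#' ascending per vertex, no self-loops) and the union-symmetrized adjacency
#' (`adj`: edge if either endpoint lists the other) used by the
#' independent-set coarsening.
#'
#' @param points numeric matrix of coordinates (rows = vertices).
#' @param k requested neighbor count (clipped to n - 1).
#' @param mode `"auto"`, `"exact"` or `"approximate"`.
#' @param seed RNG seed for the approximate index.
#' @param exact_limit point count above which `"auto"` goes approximate.
#' @param n_trees number of random-projection trees (approximate mode).
#' @param leaf_size maximum leaf size of each tree.
#' @return An object of class `aknn_graph` with fields `idx`, `dist`, `adj`,
#'   `k`, `n`, `mode`.
#' @export
build_aknn <- function(points, k, mode = "auto", seed = 1,
                       exact_limit = 10000L, n_trees = 8L, leaf_size = 32L) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2L) stop("need at least 2 points to build a neighbor graph")
  if (k < 1L) stop("k must be >= 1")
  k <- min(as.integer(k), n - 1L)
  mode <- match.arg(mode, c("auto", "exact", "approximate"))
  eff <- if (mode == "auto") (if (n > exact_limit) "approximate" else "exact")
         else mode
  nn <- if (eff == "exact") knn_exact(points, k)
        else knn_rptree(points, k, seed = seed, n_trees = n_trees,
                        leaf_size = leaf_size)
  adj <- symmetrize_adj(nn$idx, n)
  structure(list(idx = nn$idx, dist = nn$dist, adj = adj, k = k, n = n,
                 mode = eff),
            class = "aknn_graph")
}

#' @export
print.aknn_graph <- function(x, ...) {
  cat(sprintf("aknn_graph: %d vertices, k = %d, mode = %s\n",
              x$n, x$k, x$mode))
  invisible(x)
}

# exact k-NN by blockwise squared-distance expansion
knn_exact <- function(X, k, block = 512L) {
  n <- nrow(X)
  sq <- rowSums(X^2)
  idx <- matrix(0L, n, k)
  dst <- matrix(0, n, k)
  for (start in seq(1L, n, by = block)) {
    end <- min(start + block - 1L, n)
    rows <- start:end
    D2 <- outer(sq[rows], sq, "+") - 2 * X[rows, , drop = FALSE] %*% t(X)
    D2[D2 < 0] <- 0
    for (r in seq_along(rows)) {
      i <- rows[r]
      d2 <- D2[r, ]
      d2[i] <- Inf
      ord <- order(d2, seq_len(n))[seq_len(k)]
      idx[i, ] <- ord
      dst[i, ] <- sqrt(d2[ord])
    }
  }
  list(idx = idx, dist = dst)
}

# random-projection tree forest + one neighbor-of-neighbor refinement pass
knn_rptree <- function(X, k, seed = 1, n_trees = 8L, leaf_size = 32L) {
  n <- nrow(X)
  set.seed(seed)
  cand <- vector("list", n)
  split_rec <- function(members) {
    if (length(members) <= leaf_size) {
      for (i in members)
        cand[[i]] <<- c(cand[[i]], members)
      return(invisible(NULL))
    }
    dir <- stats::rnorm(ncol(X))
    proj <- as.vector(X[members, , drop = FALSE] %*% dir)
    med <- stats::median(proj)
    left <- members[proj <= med]
    right <- members[proj > med]
    if (length(left) == 0L || length(right) == 0L) { # degenerate projection
      half <- seq_len(length(members) %/% 2L)
      left <- members[half]; right <- members[-half]
    }
    split_rec(left); split_rec(right)
    invisible(NULL)
  }
  for (t in seq_len(n_trees)) split_rec(seq_len(n))

  best_from_cand <- function(i, cs) {
    cs <- unique(cs)
    cs <- cs[cs != i]
    d2 <- colSums((t(X[cs, , drop = FALSE]) - X[i, ])^2)
    ord <- order(d2, cs)[seq_len(min(k, length(cs)))]
    list(idx = cs[ord], dist = sqrt(d2[ord]))
  }
  idx <- matrix(0L, n, k); dst <- matrix(Inf, n, k)
  for (i in seq_len(n)) {
    b <- best_from_cand(i, cand[[i]])
    m <- length(b$idx)
    idx[i, seq_len(m)] <- b$idx; dst[i, seq_len(m)] <- b$dist
  }
  # refinement sweep: candidates = current neighbors + their neighbors
  for (i in seq_len(n)) {
    nb <- idx[i, idx[i, ] > 0L]
    cs <- c(nb, as.vector(idx[nb, ]))
    cs <- cs[cs > 0L]
    b <- best_from_cand(i, c(cs, nb))
    m <- length(b$idx)
    idx[i, seq_len(m)] <- b$idx; dst[i, seq_len(m)] <- b$dist
  }
  list(idx = idx, dist = dst)
}

# undirected adjacency: edge if either endpoint lists the other
symmetrize_adj <- function(idx, n) {
  from <- rep.int(seq_len(n), ncol(idx))
  to <- as.vector(idx)
  keep <- to > 0L
  from <- from[keep]; to <- to[keep]
  ft <- cbind(c(from, to), c(to, from))
  ft <- ft[!duplicated(ft) & ft[, 1] != ft[, 2], , drop = FALSE]
  adj <- split(ft[, 2], factor(ft[, 1], levels = seq_len(n)))
  lapply(adj, function(v) sort(unique(v)))
}

#' Recall of a neighbor graph against exact k-NN
#'
#' Fraction of true k-nearest neighbors recovered, averaged over vertices.
#'
#' @param graph an `aknn_graph`.
#' @param points the matrix the graph was built from.
#' @return Recall in [0, 1].
#' @export
aknn_recall <- function(graph, points) {
  truth <- knn_exact(as.matrix(points), graph$k)
  hits <- vapply(seq_len(graph$n), function(i)
    length(intersect(graph$idx[i, ], truth$idx[i, ])), 0L)
  mean(hits / graph$k)
}

#' Nearest stored neighbors of a set of vertices
#'
#' Returns the union over query vertices of their `max_neighbors` nearest
#' stored graph neighbors, excluding the query vertices themselves. Used
#' during refinement to expand inherited support vectors with their
#' level-graph neighborhood.
#'
#' @param graph an `aknn_graph`.
#' @param query_vertices integer vertex indices.
#' @param max_neighbors per-query cap on neighbors taken.
#' @return Sorted integer vertex set (possibly empty).
#' @export
nearest_in_level <- function(graph, query_vertices, max_neighbors) {
  if (max_neighbors <= 0L || length(query_vertices) == 0L) return(integer(0))
  if (any(query_vertices < 1L | query_vertices > graph$n))
    stop("query vertex out of range")
  m <- min(max_neighbors, graph$k)
  out <- unique(as.vector(graph$idx[query_vertices, seq_len(m), drop = FALSE]))
  sort(setdiff(out[out > 0L], query_vertices))
}
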