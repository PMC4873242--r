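#' Coarsening configuration
#'
#' Parameters of the multilevel training-set coarsening: the retention
#' fraction `Q` each coarsening step must keep per class, the total size at
#' which the recursion stops, and the neighbor count of the per-class graphs.
#'
#' @param Q minimum retention fraction per step, in (0, 1); default 0.5, so
#'   every coarse level keeps at least half of the finer level's points.
#' @param coarsest_bound stop once the total level size is at most this
#'   (default 500); a class already at or below `coarsest_bound / 2` is
#'   replicated unchanged while the other class keeps coarsening, which
#'   drives the coarsest level toward balance.
#' @param k neighbor count of the per-class graphs (default 10).
#' @param knn_mode neighbor search mode passed to [build_aknn()].
#' @param seed integer seed controlling the random independent-set orders.
#' @return A list of class `coarsening_config`.
#' @export
coarsening_config <- function(Q = 0.5, coarsest_bound = 500L, k = 10L,
                              knn_mode = "auto", seed = 1) {
  if (Q <= 0 || Q >= 1) stop("Q must be in (0, 1)")
  if (coarsest_bound < 2L) stop("coarsest_bound must be >= 2")
  structure(list(Q = Q, coarsest_bound = as.integer(coarsest_bound),
                 k = as.integer(k), knn_mode = knn_mode,
                 seed = as.integer(seed)),
            class = "coarsening_config")
}

#' Greedy maximal independent set
#'
#' Picks vertices of `candidate_set` in a uniformly random order, adding a
#' vertex whenever none of its graph neighbors has been added. The result
#' contains no internal edge and every excluded candidate is adjacent to a
#' member (maximality within the candidate set).
#'
#' @param graph an `aknn_graph` (its symmetrized adjacency is used).
#' @param candidate_set integer vertex subset (default: all vertices).
#' @param seed RNG seed for the greedy order.
#' @return Sorted integer vertex set.
#' @export
maximal_independent_set <- function(graph, candidate_set = seq_len(graph$n),
                                    seed = 1) {
  if (length(candidate_set) == 0L) return(integer(0))
  set.seed(seed)
  order_ <- sample(candidate_set)
  in_cand <- logical(graph$n); in_cand[candidate_set] <- TRUE
  selected <- logical(graph$n)
  blocked <- logical(graph$n)
  for (v in order_) {
    if (blocked[v]) next
    selected[v] <- TRUE
    nb <- graph$adj[[v]]
    blocked[nb[in_cand[nb]]] <- TRUE
    blocked[v] <- TRUE
  }
  which(selected)
}

#' Coarsen one class by iterated independent-set selection
#'
#' Starts from a maximal independent set of the class graph (a dominating
#' set of the class), then repeatedly adds maximal independent sets of the
#' not-yet-selected vertices until at least a fraction `Q` of the class is
#' retained. The final sweep may overshoot `Q`; the selected set always
#' dominates the class.
#'
#' @param graph an `aknn_graph` over the class points.
#' @param config a `coarsening_config`.
#' @return Sorted integer vertex set `V_hat` with `|V_hat| >= Q * n`.
#' @export
coarsen_class <- function(graph, config = coarsening_config()) {
  n <- graph$n
  v_hat <- maximal_independent_set(graph, seq_len(n), seed = config$seed)
  sweep_seed <- config$seed
  while (length(v_hat) < config$Q * n) {
    u_hat <- setdiff(seq_len(n), v_hat)
    if (length(u_hat) == 0L) break
    sweep_seed <- sweep_seed + 1L
    add <- maximal_independent_set(graph, u_hat, seed = sweep_seed)
    v_hat <- sort(c(v_hat, add))
  }
  sort(v_hat)
}

#' Build the multilevel coarsening hierarchy
#'
#' Level 0 is the full two-class training set. Each subsequent level
#' coarsens the two classes independently on their own k-NN graphs via
#' [coarsen_class()]. A class whose size has dropped to
#' `coarsest_bound / 2` or below is carried unchanged (replicated) while the
#' other class keeps shrinking, which reduces class skew down the hierarchy.
#' The recursion stops when the total level size is at most
#' `coarsest_bound`, or when no class can shrink further.
#'
#' Each level records, per class, the indices of its points in the finest
#' dataset (coarse sets are nested subsets of fine sets) and the class
#' graph, which the refinement phase reuses.
#'
#' @param dataset a binary `labeled_dataset` without missing values.
#' @param config a `coarsening_config`.
#' @return An object of class `coarsening_hierarchy`: a list with `levels`
#'   (each holding `idx_pos`, `idx_neg`, `graph_pos`, `graph_neg`,
#'   `replicated`), the `dataset`, and the `config`.
#' @export
build_hierarchy <- function(dataset, config = coarsening_config()) {
  if (!all(dataset$labels %in% c(-1L, 1L)))
    stop("hierarchy construction needs binary -1/+1 labels")
  if (any(dataset$missing_mask))
    stop("impute missing values before coarsening")
  X <- dataset$features
  min_class <- config$coarsest_bound %/% 2L
  lv <- list(idx_pos = which(dataset$labels == 1L),
             idx_neg = which(dataset$labels == -1L),
             replicated = c(pos = FALSE, neg = FALSE))
  levels <- list()
  level_seed <- config$seed
  repeat {
    lv$graph_pos <- if (length(lv$idx_pos) >= 2L)
      build_aknn(X[lv$idx_pos, , drop = FALSE], config$k,
                 mode = config$knn_mode, seed = level_seed) else NULL
    lv$graph_neg <- if (length(lv$idx_neg) >= 2L)
      build_aknn(X[lv$idx_neg, , drop = FALSE], config$k,
                 mode = config$knn_mode, seed = level_seed + 1L) else NULL
    levels[[length(levels) + 1L]] <- lv
    total <- length(lv$idx_pos) + length(lv$idx_neg)
    if (total <= config$coarsest_bound) break
    nxt <- lv
    progress <- FALSE
    for (cl in c("pos", "neg")) {
      idx <- lv[[paste0("idx_", cl)]]
      g <- lv[[paste0("graph_", cl)]]
      if (length(idx) <= min_class || is.null(g)) {
        nxt$replicated[cl] <- TRUE
        next
      }
      cfg <- config
      cfg$seed <- level_seed + if (cl == "pos") 2L else 3L
      keep <- coarsen_class(g, cfg)
      if (length(keep) < length(idx)) progress <- TRUE
      nxt[[paste0("idx_", cl)]] <- idx[keep]
      nxt$replicated[cl] <- length(keep) == length(idx)
    }
    if (!progress) break
    lv <- nxt
    level_seed <- level_seed + 10L
  }
  structure(list(levels = levels, dataset = dataset, config = config),
            class = "coarsening_hierarchy")
}

#' @export
print.coarsening_hierarchy <- function(x, ...) {
  cat(sprintf("coarsening_hierarchy: %d level(s)\n", length(x$levels)))
  for (i in seq_along(x$levels)) {
    lv <- x$levels[[i]]
    cat(sprintf("  level %d: |C+| = %d, |C-| = %d%s\n", i - 1L,
                length(lv$idx_pos), length(lv$idx_neg),
                if (any(lv$replicated)) "  (replicated)" else ""))
  }
  invisible(x)
}

#' Per-level class sizes of a hierarchy
#'
#' @param hierarchy a `coarsening_hierarchy`.
#' @return A data frame with columns `level`, `n_pos`, `n_neg`, `total`.
#' @export
hierarchy_summary <- function(hierarchy) {
  data.frame(
    level = seq_along(hierarchy$levels) - 1L,
    n_pos = vapply(hierarchy$levels, function(l) length(l$idx_pos), 0L),
    n_neg = vapply(hierarchy$levels, function(l) length(l$idx_neg), 0L),
    total = vapply(hierarchy$levels, function(l)
      length(l$idx_pos) + length(l$idx_neg), 0L)
  )
}
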