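#' Refinement configuration
#'
#' Parameters of the support-vector refinement that walks the hierarchy from
#' the coarsest level back to the finest.
#'
#' @param Q_dt size threshold below which a level's training set is retrained
#'   directly with a warm-started uniform-design search (default 500, the
#'   same size regime as the coarsest bound); at or above it, hyperparameters
#'   are inherited verbatim and training happens on pairs of nearest
#'   opposite-class clusters.
#' @param neighbor_expansion how many stored graph neighbors of each
#'   inherited support vector join the level's training set (default 5).
#' @param opposite_fraction fraction of the opposite class's clusters each
#'   cluster is paired with (default 0.10, rounded up, at least 1).
#' @param inner_folds folds of the warm-started model selection.
#' @param seed integer seed (clustering and model selection).
#' @return A list of class `refinement_config`.
#' @export
refinement_config <- function(Q_dt = 500L, neighbor_expansion = 5L,
                              opposite_fraction = 0.10, inner_folds = 5L,
                              seed = 1) {
  if (Q_dt < 2L) stop("Q_dt must be >= 2")
  if (opposite_fraction <= 0 || opposite_fraction > 1)
    stop("opposite_fraction must be in (0, 1]")
  structure(list(Q_dt = as.integer(Q_dt),
                 neighbor_expansion = as.integer(neighbor_expansion),
                 opposite_fraction = opposite_fraction,
                 inner_folds = as.integer(inner_folds),
                 seed = as.integer(seed)),
            class = "refinement_config")
}

#' Training set of a refinement level
#'
#' The inherited coarse support vectors plus, per class, up to
#' `neighbor_expansion` nearest same-class neighbors of each support vector
#' taken from the level's stored k-NN graph.
#'
#' @param level one element of `coarsening_hierarchy$levels`.
#' @param coarse_support integer indices (into the finest dataset) of the
#'   coarse solution's support vectors; must be points of this level.
#' @param config a `refinement_config`.
#' @return Sorted integer indices into the finest dataset.
#' @export
build_training_set <- function(level, coarse_support, config) {
  if (length(coarse_support) == 0L)
    stop("degenerate coarse solve: empty support set")
  out <- coarse_support
  for (cl in c("pos", "neg")) {
    idx <- level[[paste0("idx_", cl)]]
    g <- level[[paste0("graph_", cl)]]
    local <- match(intersect(coarse_support, idx), idx)
    if (length(local) == 0L || is.null(g)) next
    nb <- nearest_in_level(g, local, config$neighbor_expansion)
    out <- c(out, idx[nb])
  }
  sort(unique(out))
}

#' Pair clusters with their nearest opposite-class clusters
#'
#' Clusters each class separately with k-means; the total cluster count is
#' `max(2, floor(n / Q_dt))`, apportioned to the classes proportionally to
#' their sizes (at least 1 each, at most the class size). Every cluster is
#' paired with its `ceil(opposite_fraction * K_opposite)` nearest
#' opposite-class clusters by centroid distance.
#'
#' @param X numeric feature matrix of the level's training points.
#' @param y -1/+1 labels.
#' @param config a `refinement_config`.
#' @return A list with `assign_pos` / `assign_neg` (cluster id per point of
#'   each class, in the order of `which(y == 1)` / `which(y == -1)`),
#'   `K_pos`, `K_neg`, and `pairs`, a two-column matrix of
#'   (positive cluster, negative cluster) ids, deduplicated.
#' @export
cluster_pairing <- function(X, y, config) {
  n <- nrow(X)
  ip <- which(y == 1L); im <- which(y == -1L)
  K_total <- max(2L, n %/% config$Q_dt)
  K_pos <- max(1L, round(K_total * length(ip) / n))
  K_neg <- max(1L, K_total - K_pos)
  K_pos <- min(K_pos, length(ip))
  K_neg <- min(K_neg, length(im))
  set.seed(config$seed)
  km_pos <- stats::kmeans(X[ip, , drop = FALSE], centers = K_pos,
                          nstart = 1, iter.max = 50)
  km_neg <- stats::kmeans(X[im, , drop = FALSE], centers = K_neg,
                          nstart = 1, iter.max = 50)
  P_for <- function(K_opp) max(1L, as.integer(ceiling(
    config$opposite_fraction * K_opp)))
  cd <- as.matrix(stats::dist(rbind(km_pos$centers, km_neg$centers)))
  cd <- cd[seq_len(K_pos), K_pos + seq_len(K_neg), drop = FALSE]
  pairs <- NULL
  P_neg <- P_for(K_neg) # opposite clusters per positive cluster
  for (a in seq_len(K_pos)) {
    nearest <- order(cd[a, ])[seq_len(min(P_neg, K_neg))]
    pairs <- rbind(pairs, cbind(a, nearest))
  }
  P_pos <- P_for(K_pos)
  for (b in seq_len(K_neg)) {
    nearest <- order(cd[, b])[seq_len(min(P_pos, K_pos))]
    pairs <- rbind(pairs, cbind(nearest, b))
  }
  pairs <- unique(pairs)
  dimnames(pairs) <- list(NULL, c("pos", "neg"))
  list(assign_pos = km_pos$cluster, assign_neg = km_neg$cluster,
       K_pos = K_pos, K_neg = K_neg, pairs = pairs)
}

#' Refine the solution at one hierarchy level
#'
#' Implements one uncoarsening step: expand the inherited support vectors
#' with their level-graph neighbors; if the resulting training set is
#' smaller than `Q_dt`, rerun the nested uniform-design search warm-started
#' at the inherited (C, gamma) and train one model on it (direct branch);
#' otherwise inherit (C, gamma) verbatim, cluster the training set and train
#' a model per pair of nearest opposite-class clusters, returning the union
#' of their support vectors (clustered branch).
#'
#' @param hierarchy a `coarsening_hierarchy`.
#' @param level_index level to refine (0 = finest).
#' @param coarse_solution list with `S` (support indices into the finest
#'   dataset), `C`, `gamma`.
#' @param config a `refinement_config`.
#' @param weights_mode `"uniform"` or `"inverse-size"`.
#' @param ud_range initial (C, gamma) range for warm-started searches.
#' @return A list of class `level_solution`: `S`, `C`, `gamma`,
#'   `trained_via` (`"direct"` or `"clustered"`), `model` (direct branch
#'   only), `n_train`, `ud` (direct branch trace).
#' @export
refine_level <- function(hierarchy, level_index, coarse_solution, config,
                         weights_mode = "inverse-size",
                         ud_range = default_ud_range()) {
  level <- hierarchy$levels[[level_index + 1L]]
  data_train <- build_training_set(level, coarse_solution$S, config)
  X <- hierarchy$dataset$features[data_train, , drop = FALSE]
  y <- hierarchy$dataset$labels[data_train]
  if (length(unique(y)) < 2L)
    stop("refinement training set lost a class; increase neighbor expansion")
  make_weights <- function(C, yy)
    if (weights_mode == "uniform") weight_config(C, "uniform")
    else weight_config(C, "inverse-size", n_pos = sum(yy == 1L),
                       n_neg = sum(yy == -1L))
  if (length(data_train) < config$Q_dt) {
    ud <- nested_ud_search(X, initial_range = ud_range,
                           inner_folds = config$inner_folds,
                           initial_center = c(coarse_solution$C,
                                              coarse_solution$gamma),
                           weights_mode = weights_mode, y = y,
                           seed = config$seed + level_index)
    model <- train_wsvm(X, make_weights(ud$best_C, y),
                        gamma = ud$best_gamma, y = y)
    structure(list(S = data_train[model$support_indices],
                   C = ud$best_C, gamma = ud$best_gamma,
                   trained_via = "direct", model = model,
                   n_train = length(data_train), ud = ud),
              class = "level_solution")
  } else {
    cp <- cluster_pairing(X, y, config)
    ip <- which(y == 1L); im <- which(y == -1L)
    S <- integer(0)
    for (r in seq_len(nrow(cp$pairs))) {
      sel <- c(ip[cp$assign_pos == cp$pairs[r, "pos"]],
               im[cp$assign_neg == cp$pairs[r, "neg"]])
      yy <- y[sel]
      m <- train_wsvm(X[sel, , drop = FALSE],
                      make_weights(coarse_solution$C, yy),
                      gamma = coarse_solution$gamma, y = yy)
      S <- union(S, data_train[sel[m$support_indices]])
    }
    structure(list(S = sort(S), C = coarse_solution$C,
                   gamma = coarse_solution$gamma,
                   trained_via = "clustered", model = NULL,
                   n_train = length(data_train),
                   pairing = cp[c("K_pos", "K_neg")],
                   n_pairs = nrow(cp$pairs)),
              class = "level_solution")
  }
}

#' Project a coarsest solution through the whole hierarchy
#'
#' Applies [refine_level()] from the level below the coarsest down to the
#' finest level. If the finest level was trained on cluster pairs (so no
#' single model exists), a consolidating model is trained on the returned
#' support set with the final (C, gamma).
#'
#' @param hierarchy a `coarsening_hierarchy`.
#' @param coarsest_solution list with `S`, `C`, `gamma`, optionally `model`.
#' @param config a `refinement_config`.
#' @param weights_mode `"uniform"` or `"inverse-size"`.
#' @param ud_range initial (C, gamma) search range.
#' @return The finest `level_solution`, with a guaranteed `model` and a
#'   `log` data frame (level, branch, n_train, n_support, C, gamma).
#' @export
uncoarsen <- function(hierarchy, coarsest_solution, config,
                      weights_mode = "inverse-size",
                      ud_range = default_ud_range()) {
  r <- length(hierarchy$levels)
  sol <- coarsest_solution
  log <- list()
  if (r > 1L) {
    for (i in seq(r - 2L, 0L)) {
      sol <- refine_level(hierarchy, i, sol, config,
                          weights_mode = weights_mode, ud_range = ud_range)
      log[[length(log) + 1L]] <- data.frame(
        level = i, branch = sol$trained_via, n_train = sol$n_train,
        n_support = length(sol$S), C = sol$C, gamma = sol$gamma)
    }
  }
  if (is.null(sol$model)) {
    X <- hierarchy$dataset$features[sol$S, , drop = FALSE]
    y <- hierarchy$dataset$labels[sol$S]
    w <- if (weights_mode == "uniform") weight_config(sol$C, "uniform")
         else weight_config(sol$C, "inverse-size", n_pos = sum(y == 1L),
                            n_neg = sum(y == -1L))
    sol$model <- train_wsvm(X, w, gamma = sol$gamma, y = y)
    sol$consolidated <- TRUE
  }
  sol$log <- if (length(log)) do.call(rbind, log) else NULL
  sol
}
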