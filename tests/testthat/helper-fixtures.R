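# shared fixture builders; everything is generated in code, nothing on disk

# hand-built graph objects for coarsening tests (only $n and $adj are used)
fake_graph <- function(n, edges) {
  adj <- replicate(n, integer(0), simplify = FALSE)
  if (length(edges)) {
    for (e in edges) {
      adj[[e[1]]] <- sort(unique(c(adj[[e[1]]], e[2])))
      adj[[e[2]]] <- sort(unique(c(adj[[e[2]]], e[1])))
    }
  }
  structure(list(n = n, adj = adj, k = NA_integer_, idx = NULL,
                 dist = NULL, mode = "exact"),
            class = "aknn_graph")
}

path_graph <- function(n) {
  fake_graph(n, lapply(seq_len(n - 1), function(i) c(i, i + 1L)))
}

complete_graph <- function(n) {
  fake_graph(n, combn(n, 2, simplify = FALSE))
}

edgeless_graph <- function(n) fake_graph(n, list())

random_graph <- function(n, p, seed) {
  set.seed(seed)
  pairs <- combn(n, 2, simplify = FALSE)
  fake_graph(n, pairs[stats::runif(length(pairs)) < p])
}

# standardized twonorm fixture
std_twonorm <- function(n, d = 10, r_imb = 0.5, sep = 4, seed = 1) {
  ds <- generate_synth(synth_spec(n, d, r_imb = r_imb,
                                  class_separation = sep, seed = seed))
  apply_normalizer(fit_normalizer(ds), ds)
}

# independent fold-wise G-mean evaluation used as the re-check oracle for
# the uniform-design search
oracle_cv_gmean <- function(X, y, C, gamma, fold, weights_mode) {
  gms <- vapply(sort(unique(fold)), function(f) {
    tr <- fold != f
    ytr <- y[tr]
    if (length(unique(ytr)) < 2L) return(0)
    w <- if (weights_mode == "uniform") weight_config(C, "uniform")
         else weight_config(C, "inverse-size", n_pos = sum(ytr == 1L),
                            n_neg = sum(ytr == -1L))
    m <- train_wsvm(X[tr, , drop = FALSE], w, gamma = gamma, y = ytr)
    evaluate_predictions(y[!tr], predict(m, X[!tr, , drop = FALSE]))$G_mean
  }, 0)
  mean(gms)
}
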