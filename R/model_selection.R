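# Committed two-factor uniform-design tables. Rows give the level pair of
# each run; a level j out of m maps to the grid fraction (2j - 1) / (2m), so
# points are centered in their grid cells and all levels appear once per
# factor. The 5-run table contains the center run (3, 3): in the nested
# search its mapped point duplicates the stage-1 optimum and is evaluated
# only once, giving the 9 + 5 - 1 = 13 distinct combinations of a full
# two-stage search.
UD9_TABLE <- cbind(1:9, c(5L, 9L, 3L, 7L, 1L, 6L, 2L, 8L, 4L))
UD5_TABLE <- cbind(1:5, c(2L, 5L, 3L, 1L, 4L))

#' Uniform-design points over a (C, gamma) range
#'
#' Maps the committed 9-run or 5-run two-factor uniform-design lattice onto
#' the requested search rectangle on the log2 scale of both parameters.
#'
#' @param range list with `C_min`, `C_max`, `gamma_min`, `gamma_max`.
#' @param n_points 5 or 9.
#' @return A data frame with columns `C`, `gamma` (distinct points unless an
#'   axis is degenerate).
#' @export
ud_design_points <- function(range, n_points = 9) {
  if (!n_points %in% c(5L, 9L)) stop("n_points must be 5 or 9")
  tab <- if (n_points == 9L) UD9_TABLE else UD5_TABLE
  m <- nrow(tab)
  frac <- (2 * tab - 1) / (2 * m)
  lC <- log2(c(range$C_min, range$C_max))
  lg <- log2(c(range$gamma_min, range$gamma_max))
  data.frame(C = 2^(lC[1] + frac[, 1] * diff(lC)),
             gamma = 2^(lg[1] + frac[, 2] * diff(lg)))
}

default_ud_range <- function() {
  list(C_min = 0.01, C_max = 100, gamma_min = 0.005, gamma_max = 3.000078)
}

#' Stratified k-fold assignment
#'
#' Splits samples into `k` folds preserving class proportions; every class
#' with at least `k` members appears in every fold.
#'
#' @param y label vector.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return Integer fold id per sample.
#' @export
stratified_folds <- function(y, k, seed = 1) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# log2-scale window of given width centered on `center`, shifted (not
# truncated) to stay inside `bounds`
shift_window <- function(center, width, bounds) {
  width <- min(width, bounds[2] - bounds[1])
  lo <- center - width / 2
  hi <- center + width / 2
  if (lo < bounds[1]) { hi <- hi + (bounds[1] - lo); lo <- bounds[1] }
  if (hi > bounds[2]) { lo <- lo - (hi - bounds[2]); hi <- bounds[2] }
  c(max(lo, bounds[1]), min(hi, bounds[2]))
}

#' Nested uniform-design search for (C, gamma)
#'
#' Two-stage budgeted model selection: 9 design points over the initial
#' range, then 5 points on a half-width window recentered on the stage-1
#' optimum (clipped to the initial range). The stage-2 center duplicates the
#' stage-1 best and is not retrained, so a full search evaluates exactly 13
#' distinct combinations. Each combination is scored by the mean validation
#' G-mean of a stratified inner cross-validation with shared folds; ties
#' prefer smaller C, then smaller gamma. When `initial_center` is given
#' (hyperparameters inherited from a coarser level), stage 1 runs on a
#' half-width window around that center instead of the full initial range.
#'
#' @param dataset a binary `labeled_dataset` (or matrix with `y`).
#' @param initial_range list with `C_min`, `C_max`, `gamma_min`,
#'   `gamma_max`; defaults to C in [0.01, 100] and gamma in
#'   [0.005, 3.000078].
#' @param inner_folds number of validation folds (default 5).
#' @param initial_center optional `c(C, gamma)` warm-start center.
#' @param weights_mode `"uniform"` or `"inverse-size"` class weighting used
#'   for every trained candidate.
#' @param y optional labels when `dataset` is a matrix.
#' @param seed RNG seed (fold assignment).
#' @return A list of class `ud_result`: `best_C`, `best_gamma`,
#'   `best_gmean`, `n_evaluated`, `trace` (data frame: stage, C, gamma,
#'   gmean).
#' @export
nested_ud_search <- function(dataset, initial_range = default_ud_range(),
                             inner_folds = 5, initial_center = NULL,
                             weights_mode = "inverse-size", y = NULL,
                             seed = 1) {
  if (inherits(dataset, "labeled_dataset")) {
    X <- dataset$features; y <- dataset$labels
  } else X <- as.matrix(dataset)
  if (length(unique(y)) < 2L) stop("both classes required for model selection")
  fold <- stratified_folds(y, inner_folds, seed = seed)
  if (min(table(y)) < inner_folds)
    fold <- stratified_folds(y, max(2L, min(table(y))), seed = seed)

  cache <- new.env(parent = emptyenv())
  trace <- list()
  eval_point <- function(C, gamma, stage) {
    key <- sprintf("%.12e_%.12e", C, gamma)
    if (!is.null(cache[[key]])) return(cache[[key]])
    gms <- vapply(sort(unique(fold)), function(f) {
      tr <- fold != f; te <- !tr
      ytr <- y[tr]
      if (length(unique(ytr)) < 2L || length(unique(y[te])) < 2L) return(0)
      w <- if (weights_mode == "uniform") weight_config(C, "uniform")
           else weight_config(C, "inverse-size", n_pos = sum(ytr == 1L),
                              n_neg = sum(ytr == -1L))
      m <- train_wsvm(X[tr, , drop = FALSE], w, gamma = gamma, y = ytr)
      evaluate_predictions(y[te],
                           predict(m, X[te, , drop = FALSE]))$G_mean
    }, 0)
    gm <- mean(gms)
    cache[[key]] <- gm
    trace[[length(trace) + 1L]] <<- data.frame(stage = stage, C = C,
                                               gamma = gamma, gmean = gm)
    gm
  }

  bC <- log2(c(initial_range$C_min, initial_range$C_max))
  bg <- log2(c(initial_range$gamma_min, initial_range$gamma_max))
  if (is.null(initial_center)) {
    w1C <- bC; w1g <- bg
  } else {
    w1C <- shift_window(log2(initial_center[1]), diff(bC) / 2, bC)
    w1g <- shift_window(log2(initial_center[2]), diff(bg) / 2, bg)
  }
  r1 <- list(C_min = 2^w1C[1], C_max = 2^w1C[2],
             gamma_min = 2^w1g[1], gamma_max = 2^w1g[2])
  p1 <- unique(ud_design_points(r1, 9))
  for (i in seq_len(nrow(p1))) eval_point(p1$C[i], p1$gamma[i], 1L)

  pick_best <- function() {
    tr <- do.call(rbind, trace)
    tr <- tr[order(-tr$gmean, tr$C, tr$gamma), ]
    tr[1, ]
  }
  best1 <- pick_best()

  w2C <- shift_window(log2(best1$C), diff(w1C) / 2, bC)
  w2g <- shift_window(log2(best1$gamma), diff(w1g) / 2, bg)
  r2 <- list(C_min = 2^w2C[1], C_max = 2^w2C[2],
             gamma_min = 2^w2g[1], gamma_max = 2^w2g[2])
  p2 <- ud_design_points(r2, 5)
  # the center run of the 5-point table is the duplicate of the stage-1 best
  p2$C[3] <- best1$C; p2$gamma[3] <- best1$gamma
  p2 <- unique(p2)
  for (i in seq_len(nrow(p2))) eval_point(p2$C[i], p2$gamma[i], 2L)

  best <- pick_best()
  tr <- do.call(rbind, trace)
  structure(list(best_C = best$C, best_gamma = best$gamma,
                 best_gmean = best$gmean,
                 n_evaluated = length(ls(cache)), trace = tr),
            class = "ud_result")
}

#' @export
print.ud_result <- function(x, ...) {
  cat(sprintf(
    "ud_result: best C = %.4g, gamma = %.4g (G-mean %.4f, %d combos)\n",
    x$best_C, x$best_gamma, x$best_gmean, x$n_evaluated))
  invisible(x)
}
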