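#' Regularized EM imputation by iterated ridge regression
#'
#' Fills missing entries by an expectation-maximization scheme whose
#' conditional regressions are ridge-regularized: starting from per-feature
#' mean imputation, each iteration re-estimates the mean and covariance of
#' the completed data, then, for every distinct missingness pattern,
#' regresses the pattern's missing features on its observed features with a
#' ridge penalty chosen by generalized cross-validation (GCV) over a log
#' grid, and replaces the missing cells with the regression predictions.
#' Iterations stop when the largest relative change of the imputed values
#' falls below `tol` or after `max_iter` iterations. Observed entries are
#' never modified.
#'
#' @param dataset a `labeled_dataset`; labels are excluded from all
#'   regressions.
#' @param tol relative-change convergence threshold (default 1e-4).
#' @param max_iter maximum EM iterations (default 50).
#' @param ridge_grid candidate ridge penalties (on the Gram-matrix scale)
#'   searched by GCV per regression.
#' @return A list with `dataset` (completed, empty missing mask) and
#'   `model` (class `rem_model`: `mean`, `covariance`, `ridge_params`,
#'   `n_train`, `n_iter`, `converged`, `history`).
#' @export
rem_fit_transform <- function(dataset, tol = 1e-4, max_iter = 50,
                              ridge_grid = 10^seq(-4, 2, length.out = 13)) {
  X <- dataset$features
  M <- dataset$missing_mask
  n <- nrow(X); d <- ncol(X)
  never <- which(colSums(!M) == 0L)
  if (length(never))
    stop("unimputable-feature error: feature(s) never observed: ",
         paste(never, collapse = ", "))
  if (!any(M)) {
    model <- structure(list(mean = colMeans(X), covariance = stats::cov(X),
                            ridge_params = numeric(0), n_train = n,
                            n_iter = 0L, converged = TRUE,
                            history = numeric(0)),
                       class = "rem_model")
    return(list(dataset = dataset, model = model))
  }
  # initialization: observed-mean imputation
  mu0 <- apply(X, 2, mean, na.rm = TRUE)
  Xc <- X
  for (j in seq_len(d)) Xc[M[, j], j] <- mu0[j]

  miss_rows <- which(rowSums(M) > 0L)
  pattern_key <- apply(M[miss_rows, , drop = FALSE], 1,
                       function(r) paste(which(r), collapse = ","))
  pattern_rows <- split(miss_rows, pattern_key)

  history <- numeric(0)
  ridge_used <- stats::setNames(numeric(length(pattern_rows)),
                                names(pattern_rows))
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    old_imputed <- Xc[M]
    mu <- colMeans(Xc)
    Z <- sweep(Xc, 2, mu, "-")
    for (p in names(pattern_rows)) {
      rows <- pattern_rows[[p]]
      m_cols <- as.integer(strsplit(p, ",", fixed = TRUE)[[1]])
      o_cols <- setdiff(seq_len(d), m_cols)
      if (length(o_cols) == 0L) next
      fit <- ridge_gcv(Z[, o_cols, drop = FALSE], Z[, m_cols, drop = FALSE],
                       ridge_grid)
      ridge_used[p] <- fit$lambda
      Xc[rows, m_cols] <- rep(mu[m_cols], each = length(rows)) +
        Z[rows, o_cols, drop = FALSE] %*% fit$B
    }
    delta <- max(abs(Xc[M] - old_imputed)) /
      max(max(abs(Xc[M])), .Machine$double.eps)
    history <- c(history, delta)
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("REM did not converge in ", max_iter,
            " iterations; returning last iterate")
  model <- structure(list(mean = colMeans(Xc), covariance = stats::cov(Xc),
                          ridge_params = ridge_used, n_train = n,
                          n_iter = iter, converged = converged,
                          history = history),
                     class = "rem_model")
  completed <- labeled_dataset(Xc, dataset$labels,
                               matrix(FALSE, n, d),
                               feature_names = dataset$feature_names,
                               class_map = dataset$class_map)
  list(dataset = completed, model = model)
}

# multivariate ridge regression A -> Y (both centered) with GCV choice of
# the penalty; returns coefficients of the best lambda
ridge_gcv <- function(A, Y, grid) {
  n <- nrow(A)
  e <- eigen(crossprod(A), symmetric = TRUE)
  d2 <- pmax(e$values, 0)
  V <- e$vectors
  G <- crossprod(V, crossprod(A, Y))
  best <- NULL; best_gcv <- Inf
  for (lam in sort(grid)) {
    B <- V %*% (G / (d2 + lam))
    rss <- sum((Y - A %*% B)^2)
    df <- sum(d2 / (d2 + lam))
    gcv <- (rss / n) / (1 - df / n)^2
    if (gcv < best_gcv - 1e-15) {
      best_gcv <- gcv; best <- list(B = B, lambda = lam)
    }
  }
  best
}

#' @export
print.rem_model <- function(x, ...) {
  cat(sprintf("rem_model: %d iteration(s), converged = %s\n",
              x$n_iter, x$converged))
  invisible(x)
}

#' Impute new data with a fitted REM model
#'
#' One conditional-mean pass using the training-fold mean and covariance:
#' for each missingness pattern the missing block is predicted as
#' `mu_m + (x_o - mu_o) (Sigma_oo + ridge I)^(-1) Sigma_om`. No statistic of
#' the new data is used, so applying the model to held-out folds transfers
#' no information from them.
#'
#' @param model a fitted `rem_model`.
#' @param dataset a `labeled_dataset` with matching feature count.
#' @param ridge penalty added to `Sigma_oo` (default: the fitted
#'   per-pattern GCV penalties rescaled to the covariance scale, or 1e-6).
#' @return The completed `labeled_dataset`.
#' @export
apply_imputer <- function(model, dataset, ridge = NULL) {
  X <- dataset$features
  M <- dataset$missing_mask
  d <- ncol(X)
  if (length(model$mean) != d) stop("shape error: feature count mismatch")
  if (!any(M)) return(dataset)
  if (is.null(ridge)) {
    ridge <- if (length(model$ridge_params))
      stats::median(model$ridge_params) / max(model$n_train - 1, 1)
    else 1e-6
  }
  S <- model$covariance
  mu <- model$mean
  miss_rows <- which(rowSums(M) > 0L)
  key <- apply(M[miss_rows, , drop = FALSE], 1,
               function(r) paste(which(r), collapse = ","))
  for (p in unique(key)) {
    rows <- miss_rows[key == p]
    m_cols <- as.integer(strsplit(p, ",", fixed = TRUE)[[1]])
    o_cols <- setdiff(seq_len(d), m_cols)
    if (length(o_cols) == 0L)
      stop("sample with all features missing cannot be imputed")
    B <- solve(S[o_cols, o_cols, drop = FALSE] +
                 diag(ridge, length(o_cols)),
               S[o_cols, m_cols, drop = FALSE])
    Zo <- sweep(X[rows, o_cols, drop = FALSE], 2, mu[o_cols], "-")
    X[rows, m_cols] <- rep(mu[m_cols], each = length(rows)) + Zo %*% B
  }
  labeled_dataset(X, dataset$labels, matrix(FALSE, nrow(X), d),
                  feature_names = dataset$feature_names,
                  class_map = dataset$class_map)
}

#' Per-feature mean imputation (baseline)
#'
#' @param dataset a `labeled_dataset`.
#' @return The dataset with missing cells replaced by the observed mean of
#'   their feature.
#' @export
mean_impute <- function(dataset) {
  X <- dataset$features
  M <- dataset$missing_mask
  if (!any(M)) return(dataset)
  mu <- apply(X, 2, mean, na.rm = TRUE)
  for (j in seq_len(ncol(X))) X[M[, j], j] <- mu[j]
  labeled_dataset(X, dataset$labels, matrix(FALSE, nrow(X), ncol(X)),
                  feature_names = dataset$feature_names,
                  class_map = dataset$class_map)
}
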