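#' Specification for a synthetic imbalanced Gaussian-mixture dataset
#'
#' Describes the benchmark-style fixtures the package generates: two (or
#' more) Gaussian classes with a controlled imbalance ratio, class
#' separation, and optional equicorrelation between features.
#'
#' Structures:
#' \describe{
#'   \item{`twonorm`}{two unit-covariance Gaussians at opposite means
#'     `+/- (sep/2)/sqrt(d) * 1`; at the default separation 4 this is the
#'     classical twonorm benchmark (means at `+/- 2/sqrt(d)`).}
#'   \item{`ringnorm`}{one class `N(0, 4I)`, the other
#'     `N((sep/2)/sqrt(d) * 1, I)`, the classical ringnorm geometry.}
#'   \item{`blobs`}{`n_classes` spherical Gaussians on a scaled simplex,
#'     for multiclass (one-against-all) testing.}
#' }
#'
#' @param n_samples total number of samples (>= 4).
#' @param n_features feature dimension.
#' @param r_imb majority-class fraction in [0.5, 1) (binary structures).
#' @param class_separation Euclidean distance between class means in units
#'   of within-class standard deviation.
#' @param structure one of `"twonorm"`, `"ringnorm"`, `"blobs"`.
#' @param correlation equicorrelation rho in [0, 1) between features.
#' @param n_classes number of blobs (structure `"blobs"` only).
#' @param priors optional class priors for `"blobs"`.
#' @param seed integer RNG seed.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(n_samples, n_features = 20, r_imb = 0.5,
                       class_separation = 4, structure = "twonorm",
                       correlation = 0, n_classes = 2, priors = NULL,
                       seed = 1) {
  structure_ <- match.arg(structure, c("twonorm", "ringnorm", "blobs"))
  if (n_samples < 4) stop("spec error: n_samples must be >= 4")
  if (structure_ != "blobs") {
    if (r_imb < 0.5 || r_imb >= 1) stop("spec error: r_imb must be in [0.5, 1)")
    if ((1 - r_imb) * n_samples < 1)
      stop("spec error: infeasible imbalance, minority class empty")
  }
  if (correlation < 0 || correlation >= 1)
    stop("spec error: correlation must be in [0, 1)")
  structure(list(n_samples = as.integer(n_samples),
                 n_features = as.integer(n_features),
                 r_imb = r_imb, class_separation = class_separation,
                 structure = structure_, correlation = correlation,
                 n_classes = as.integer(n_classes), priors = priors,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

# n x d standard-normal draws with equicorrelation rho:
# x = sqrt(rho) * z0 + sqrt(1 - rho) * z keeps unit marginal variance.
rnorm_equicorr <- function(n, d, rho) {
  Z <- matrix(stats::rnorm(n * d), n, d)
  if (rho > 0) {
    z0 <- stats::rnorm(n)
    Z <- sqrt(rho) * z0 + sqrt(1 - rho) * Z
  }
  Z
}

#' Generate a synthetic labeled dataset
#'
#' Draws the Gaussian mixture described by a [synth_spec()]. Binary
#' structures label the minority class +1 and the majority -1; class counts
#' match `r_imb` up to rounding. Identical spec and seed give an identical
#' dataset.
#'
#' @param spec a `synth_spec`.
#' @return A `labeled_dataset`.
#' @export
generate_synth <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples; d <- spec$n_features
  if (spec$structure == "blobs") {
    k <- spec$n_classes
    priors <- spec$priors %||% rep(1 / k, k)
    priors <- priors / sum(priors)
    counts <- floor(priors * n)
    rem <- n - sum(counts)
    if (rem > 0) counts[order(priors * n - counts,
                              decreasing = TRUE)[seq_len(rem)]] <-
        counts[order(priors * n - counts, decreasing = TRUE)[seq_len(rem)]] + 1L
    # class centers on a simplex scaled to the requested separation
    centers <- diag(1, k, d) * spec$class_separation / sqrt(2)
    X <- NULL; y <- integer(0)
    for (c_ in seq_len(k)) {
      Xi <- rnorm_equicorr(counts[c_], d, spec$correlation)
      Xi <- sweep(Xi, 2, centers[c_, ], "+")
      X <- rbind(X, Xi); y <- c(y, rep.int(c_, counts[c_]))
    }
    perm <- sample.int(n)
    return(labeled_dataset(X[perm, , drop = FALSE], y[perm]))
  }
  n_maj <- round(spec$r_imb * n)
  n_min <- n - n_maj
  mu <- rep(spec$class_separation / 2 / sqrt(d), d)
  if (spec$structure == "twonorm") {
    X_min <- sweep(rnorm_equicorr(n_min, d, spec$correlation), 2, mu, "+")
    X_maj <- sweep(rnorm_equicorr(n_maj, d, spec$correlation), 2, -mu, "+")
  } else { # ringnorm: majority N(0, 4I), minority N(mu, I)
    X_min <- sweep(rnorm_equicorr(n_min, d, spec$correlation), 2, 2 * mu, "+")
    X_maj <- 2 * rnorm_equicorr(n_maj, d, spec$correlation)
  }
  X <- rbind(X_min, X_maj)
  y <- c(rep.int(1L, n_min), rep.int(-1L, n_maj))
  perm <- sample.int(n)
  labeled_dataset(X[perm, , drop = FALSE], y[perm])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Inject missing values completely at random
#'
#' Masks exactly `round(r_mv * n * d)` feature cells chosen uniformly
#' without replacement (exact-count MCAR, so the achieved missingness ratio
#' is deterministic). Labels are never masked. If the draw would empty an
#' entire row, cells are moved to other rows so every sample keeps at least
#' one observed feature.
#'
#' @param dataset a `labeled_dataset`.
#' @param r_mv missingness ratio in [0, 1).
#' @param seed integer RNG seed.
#' @return The dataset with an enlarged missing mask.
#' @export
inject_missing <- function(dataset, r_mv, seed = 1) {
  if (r_mv < 0 || r_mv >= 1) stop("r_mv must be in [0, 1)")
  if (r_mv == 0) return(dataset)
  n <- n_samples(dataset); d <- n_features(dataset)
  n_mask <- round(r_mv * n * d)
  if (n_mask > n * (d - 1))
    stop("r_mv too high: some row would lose all features")
  set.seed(seed)
  cells <- sample.int(n * d, n_mask)
  mask <- matrix(FALSE, n, d)
  mask[cells] <- TRUE
  # keep >= 1 observed feature per row: move surplus cells to rows with room
  full <- which(rowSums(mask) == d)
  if (length(full)) {
    for (i in full) {
      keep <- sample.int(d, 1L)
      mask[i, keep] <- FALSE
      room <- which(rowSums(mask) < d - 1L)
      room <- room[room != i]
      j <- room[sample.int(length(room), 1L)]
      free <- which(!mask[j, ])
      mask[j, free[sample.int(length(free), 1L)]] <- TRUE
    }
  }
  new_mask <- dataset$missing_mask | mask
  X <- dataset$features
  X[new_mask] <- NA_real_
  labeled_dataset(X, dataset$labels, new_mask,
                  feature_names = dataset$feature_names,
                  class_map = dataset$class_map)
}
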