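#' RBF (Gaussian) kernel
#'
#' `k(x, z) = exp(-gamma * ||x - z||^2)`, the kernel used by every SVM in
#' the package. At `gamma = 0` the kernel is constant 1.
#'
#' @param x,z numeric vectors of equal length, or matrices with matching
#'   column count (row-wise kernel matrix is returned).
#' @param gamma bandwidth parameter, >= 0.
#' @return Kernel value(s) in (0, 1].
#' @export
rbf_kernel <- function(x, z, gamma) {
  if (gamma < 0) stop("parameter error: gamma must be >= 0")
  if (is.matrix(x) || is.matrix(z)) {
    x <- rbind(x); z <- rbind(z)
    if (ncol(x) != ncol(z)) stop("dimension mismatch")
    d2 <- outer(rowSums(x^2), rowSums(z^2), "+") - 2 * x %*% t(z)
    d2[d2 < 0] <- 0
    exp(-gamma * d2)
  } else {
    if (length(x) != length(z)) stop("dimension mismatch")
    exp(-gamma * sum((x - z)^2))
  }
}

#' Per-class penalty configuration for the weighted SVM
#'
#' Resolves the base penalty `C` into class penalties `C_plus` (minority,
#' label +1) and `C_minus` (majority). The inverse-size mode sets
#' `C_plus = C * l / (2 n_plus)` and `C_minus = C * l / (2 n_minus)` so the
#' rarer class is penalized harder and the total penalty mass is balanced
#' across classes; uniform mode reduces the weighted SVM to the standard
#' soft-margin SVM.
#'
#' @param C base penalty, > 0.
#' @param mode `"uniform"`, `"inverse-size"` or `"explicit"`.
#' @param n_pos,n_neg class sizes (required for `"inverse-size"`).
#' @param C_plus,C_minus explicit per-class penalties (mode `"explicit"`).
#' @return A list of class `weight_config` with `C`, `mode`, `C_plus`,
#'   `C_minus`.
#' @export
weight_config <- function(C = 1, mode = "inverse-size", n_pos = NULL,
                          n_neg = NULL, C_plus = NULL, C_minus = NULL) {
  if (C <= 0) stop("C must be positive")
  mode <- match.arg(mode, c("uniform", "inverse-size", "explicit"))
  if (mode == "uniform") {
    C_plus <- C; C_minus <- C
  } else if (mode == "inverse-size") {
    if (is.null(n_pos) || is.null(n_neg))
      stop("inverse-size weighting needs class sizes")
    l <- n_pos + n_neg
    C_plus <- C * l / (2 * n_pos)
    C_minus <- C * l / (2 * n_neg)
  } else if (is.null(C_plus) || is.null(C_minus)) {
    stop("explicit mode needs C_plus and C_minus")
  }
  if (C_plus <= 0 || C_minus <= 0) stop("class penalties must be positive")
  structure(list(C = C, mode = mode, C_plus = C_plus, C_minus = C_minus),
            class = "weight_config")
}

#' Train a (weighted) soft-margin SVM with RBF kernel
#'
#' Solves the dual of the cost-sensitive SVM in which positive- and
#' negative-class slacks carry separate penalties `C_plus`, `C_minus`
#' (equal penalties recover the standard SVM). The quadratic program is
#' delegated to the libsvm solver; the fitted model is repackaged so that
#' the decision function, support vectors and dual coefficients are exposed
#' in the package's own orientation: `decision_value > 0` predicts +1.
#'
#' @param dataset a binary -1/+1 `labeled_dataset` without missing values,
#'   or a feature matrix when `y` is given.
#' @param weights a `weight_config`; default uniform with C = 1.
#' @param gamma RBF bandwidth.
#' @param y optional label vector when `dataset` is a plain matrix.
#' @param tolerance libsvm termination tolerance.
#' @return An object of class `wsvm_model`: `support_vectors`,
#'   `support_indices`, `dual_coefs` (signed alpha_i y_i), `b`, `gamma`,
#'   `weights`, `training_size`.
#' @export
train_wsvm <- function(dataset, weights = weight_config(mode = "uniform"),
                       gamma = 0.1, y = NULL, tolerance = 1e-3) {
  if (inherits(dataset, "labeled_dataset")) {
    if (any(dataset$missing_mask))
      stop("contract violation: impute missing values before training")
    X <- dataset$features; y <- dataset$labels
  } else {
    X <- as.matrix(dataset)
  }
  if (!all(y %in% c(-1L, 1L))) stop("labels must be -1/+1")
  if (length(unique(y)) < 2L)
    stop("training error: both classes must be present")
  yf <- factor(y, levels = c(-1L, 1L))
  cw <- c(`-1` = weights$C_minus / weights$C, `1` = weights$C_plus / weights$C)
  fit <- e1071::svm(X, yf, type = "C-classification", kernel = "radial",
                    gamma = gamma, cost = weights$C, class.weights = cw,
                    scale = FALSE, tolerance = tolerance)
  sv <- fit$SV
  coefs <- as.vector(fit$coefs)
  b <- -fit$rho
  # orient so that decision > 0 <=> class +1: libsvm's internal sign follows
  # the class it saw first, so check against its own training predictions
  f_tr <- as.vector(rbf_kernel(X, sv, gamma) %*% coefs) + b
  pred <- as.integer(as.character(stats::predict(fit, X)))
  if (mean(sign(f_tr + 1e-15) == pred) < 0.5) {
    coefs <- -coefs; b <- -b
  }
  structure(list(support_vectors = sv,
                 support_indices = as.integer(fit$index),
                 dual_coefs = coefs, b = b,
                 gamma = gamma, weights = weights,
                 training_size = nrow(X)),
            class = "wsvm_model")
}

#' Decision values of a trained (weighted) SVM
#'
#' `f(x) = sum_i alpha_i y_i k(sv_i, x) + b`; positive values predict the
#' minority (+1) class.
#'
#' @param model a `wsvm_model`.
#' @param x numeric matrix (rows = query points) or a single vector.
#' @return Numeric vector of decision values.
#' @export
decision_value <- function(model, x) {
  x <- rbind(x)
  if (ncol(x) != ncol(model$support_vectors)) stop("dimension mismatch")
  as.vector(rbf_kernel(x, model$support_vectors, model$gamma) %*%
              model$dual_coefs) + model$b
}

#' Predict class labels
#'
#' Sign of the decision value, with ties (exact zero) resolved to +1, the
#' minority class.
#'
#' @param object a `wsvm_model`.
#' @param newdata numeric matrix or vector of query points.
#' @param ... unused.
#' @return Integer labels in \{-1, +1\}.
#' @export
predict.wsvm_model <- function(object, newdata, ...) {
  f <- decision_value(object, newdata)
  ifelse(f >= 0, 1L, -1L)
}

#' @export
print.wsvm_model <- function(x, ...) {
  cat(sprintf(
    "wsvm_model: %d support vectors / %d training points, gamma = %g\n",
    length(x$dual_coefs), x$training_size, x$gamma))
  cat(sprintf("  C+ = %g, C- = %g (%s)\n", x$weights$C_plus,
              x$weights$C_minus, x$weights$mode))
  invisible(x)
}

# dual objective sum(alpha) - 1/2 sum_ij alpha_i alpha_j y_i y_j K_ij,
# recomputed from the stored signed coefficients (alpha_i = |coef_i|)
dual_objective <- function(model) {
  s <- model$dual_coefs
  K <- rbf_kernel(model$support_vectors, model$support_vectors, model$gamma)
  sum(abs(s)) - 0.5 * as.numeric(t(s) %*% K %*% s)
}
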