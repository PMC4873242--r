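#' Multilevel (W)SVM configuration
#'
#' Bundles every tunable of the end-to-end pipeline. The defaults reproduce
#' the framework's standard protocol: k = 10 neighbor graphs, retention
#' Q = 0.5, coarsest bound 500, C in [0.01, 100] and gamma in
#' [0.005, 3.000078] on the log2 scale, 9 + 5 nested uniform design,
#' inverse-class-size weights, 10 stratified outer folds.
#'
#' @param weighted `TRUE` for the cost-sensitive MLWSVM (inverse-class-size
#'   penalties), `FALSE` for the plain MLSVM.
#' @param coarsening a [coarsening_config()].
#' @param refinement a [refinement_config()].
#' @param ud_range initial (C, gamma) search range.
#' @param inner_folds validation folds inside the uniform-design search.
#' @param outer_folds folds of [mlsvm_cross_validate()].
#' @param normalize_global `TRUE` standardizes the whole dataset before
#'   fold splitting (the benchmark preprocessing); `FALSE` (default) fits
#'   the normalizer on each training fold only.
#' @param seed master seed; all stage seeds derive from it.
#' @return A list of class `mlsvm_config`.
#' @export
mlsvm_config <- function(weighted = TRUE,
                         coarsening = NULL, refinement = NULL,
                         ud_range = default_ud_range(),
                         inner_folds = 5L, outer_folds = 10L,
                         normalize_global = FALSE, seed = 1) {
  seed <- as.integer(seed)
  if (is.null(coarsening)) coarsening <- coarsening_config(seed = seed)
  if (is.null(refinement))
    refinement <- refinement_config(inner_folds = inner_folds, seed = seed)
  structure(list(weighted = weighted, coarsening = coarsening,
                 refinement = refinement, ud_range = ud_range,
                 inner_folds = as.integer(inner_folds),
                 outer_folds = as.integer(outer_folds),
                 normalize_global = normalize_global, seed = seed),
            class = "mlsvm_config")
}

weights_mode_of <- function(config) {
  if (config$weighted) "inverse-size" else "uniform"
}

#' Fit a multilevel (weighted) SVM
#'
#' Datasets at or below the coarsest bound are solved directly: one nested
#' uniform-design search plus one (weighted) SVM, exactly as if
#' [nested_ud_search()] and [train_wsvm()] were called by hand with the same
#' seed. Larger datasets go through the three-phase pipeline: per-class
#' graph coarsening into a hierarchy, model selection and training at the
#' coarsest level, then support-vector refinement back to the finest level.
#'
#' @param dataset a binary -1/+1 `labeled_dataset`, imputed and normalized.
#' @param config an `mlsvm_config`.
#' @return An object of class `mlsvm_model`: final `model` (a
#'   `wsvm_model`), `C`, `gamma`, `S` (final support indices), `depth`
#'   (hierarchy levels), `hierarchy_sizes`, `refinement_log`, `config`.
#' @export
mlsvm_fit <- function(dataset, config = mlsvm_config()) {
  if (any(dataset$missing_mask))
    stop("impute missing values before fitting (see rem_fit_transform)")
  if (!all(dataset$labels %in% c(-1L, 1L)))
    stop("binary -1/+1 labels required; see mlsvm_fit_multiclass")
  wm <- weights_mode_of(config)
  n <- n_samples(dataset)
  if (n <= config$coarsening$coarsest_bound) {
    ud <- nested_ud_search(dataset, initial_range = config$ud_range,
                           inner_folds = config$inner_folds,
                           weights_mode = wm, seed = config$seed)
    y <- dataset$labels
    w <- if (wm == "uniform") weight_config(ud$best_C, "uniform")
         else weight_config(ud$best_C, "inverse-size",
                            n_pos = sum(y == 1L), n_neg = sum(y == -1L))
    model <- train_wsvm(dataset, w, gamma = ud$best_gamma)
    return(structure(list(model = model, C = ud$best_C,
                          gamma = ud$best_gamma,
                          S = model$support_indices, depth = 1L,
                          hierarchy_sizes = data.frame(
                            level = 0L, n_pos = sum(y == 1L),
                            n_neg = sum(y == -1L), total = n),
                          refinement_log = NULL, ud = ud,
                          config = config),
                     class = "mlsvm_model"))
  }
  hier <- build_hierarchy(dataset, config$coarsening)
  r <- length(hier$levels)
  coarse_lv <- hier$levels[[r]]
  idx_r <- sort(c(coarse_lv$idx_pos, coarse_lv$idx_neg))
  Xr <- dataset$features[idx_r, , drop = FALSE]
  yr <- dataset$labels[idx_r]
  ud <- nested_ud_search(Xr, initial_range = config$ud_range,
                         inner_folds = config$inner_folds,
                         weights_mode = wm, y = yr, seed = config$seed)
  w <- if (wm == "uniform") weight_config(ud$best_C, "uniform")
       else weight_config(ud$best_C, "inverse-size",
                          n_pos = sum(yr == 1L), n_neg = sum(yr == -1L))
  coarse_model <- train_wsvm(Xr, w, gamma = ud$best_gamma, y = yr)
  coarsest <- list(S = idx_r[coarse_model$support_indices],
                   C = ud$best_C, gamma = ud$best_gamma,
                   model = coarse_model)
  sol <- uncoarsen(hier, coarsest, config$refinement,
                   weights_mode = wm, ud_range = config$ud_range)
  structure(list(model = sol$model, C = sol$C, gamma = sol$gamma,
                 S = sol$S, depth = r,
                 hierarchy_sizes = hierarchy_summary(hier),
                 refinement_log = sol$log, ud = ud, config = config),
            class = "mlsvm_model")
}

#' @export
print.mlsvm_model <- function(x, ...) {
  cat(sprintf(
    "mlsvm_model: depth %d, C = %.4g, gamma = %.4g, %d support vectors\n",
    x$depth, x$C, x$gamma, length(x$model$dual_coefs)))
  invisible(x)
}

#' Predict with a multilevel model
#'
#' @param object an `mlsvm_model`.
#' @param newdata feature matrix or `labeled_dataset`.
#' @param ... unused.
#' @return Integer labels in \{-1, +1\}.
#' @export
predict.mlsvm_model <- function(object, newdata, ...) {
  if (inherits(newdata, "labeled_dataset")) newdata <- newdata$features
  predict(object$model, newdata)
}

#' Decision values of a multilevel model
#'
#' @param model an `mlsvm_model`.
#' @param x feature matrix.
#' @return Numeric decision values (positive predicts +1).
#' @export
mlsvm_decision <- function(model, x) {
  if (inherits(x, "labeled_dataset")) x <- x$features
  decision_value(model$model, x)
}

#' One-against-all multilevel multiclass model
#'
#' Trains one binary multilevel model per class, that class relabelled +1
#' against the rest as -1; prediction picks the class with the maximal
#' decision value.
#'
#' @param dataset a `labeled_dataset` with >= 3 classes.
#' @param config an `mlsvm_config`.
#' @return An object of class `mlsvm_ova_model` with one `mlsvm_model` per
#'   class.
#' @export
mlsvm_fit_multiclass <- function(dataset, config = mlsvm_config()) {
  classes <- sort(unique(dataset$labels))
  if (length(classes) < 3L)
    stop("use mlsvm_fit for binary problems")
  models <- lapply(classes, function(cl) {
    y_bin <- ifelse(dataset$labels == cl, 1L, -1L)
    d_bin <- labeled_dataset(dataset$features, y_bin,
                             dataset$missing_mask)
    mlsvm_fit(d_bin, config)
  })
  structure(list(classes = classes, models = models, config = config),
            class = "mlsvm_ova_model")
}

#' @export
predict.mlsvm_ova_model <- function(object, newdata, ...) {
  if (inherits(newdata, "labeled_dataset")) newdata <- newdata$features
  dv <- vapply(object$models, function(m) mlsvm_decision(m, newdata),
               numeric(nrow(rbind(newdata))))
  dv <- rbind(dv)
  object$classes[max.col(dv, ties.method = "first")]
}

#' Cross-validated evaluation of the multilevel pipeline
#'
#' Stratified outer k-fold protocol for data that may contain missing
#' values. Within each fold: the normalizer is fitted on the training
#' split's observed entries (unless `normalize_global`), the REM imputer is
#' fitted on the training split and applied with frozen parameters to the
#' held-out split, a multilevel model is fitted on the completed training
#' data, and performance is measured on the held-out fold. Aggregate
#' metrics are per-fold arithmetic means by default, or pooled over all
#' held-out predictions with `pooled = TRUE`.
#'
#' @param dataset a binary -1/+1 `labeled_dataset` (missing values
#'   allowed).
#' @param config an `mlsvm_config`.
#' @param pooled pool held-out predictions before computing metrics instead
#'   of averaging per-fold metrics.
#' @return A list of class `mlsvm_cv_result`: `folds` (per-fold
#'   `metrics_report`s), `aggregate` (named numeric: SN, SP, G_mean, ACC),
#'   `pooled`, `rem_models`, `fold_id`, `config`.
#' @export
mlsvm_cross_validate <- function(dataset, config = mlsvm_config(),
                                 pooled = FALSE) {
  y <- dataset$labels
  fold <- stratified_folds(y, config$outer_folds, seed = config$seed)
  ds <- dataset
  if (config$normalize_global)
    ds <- apply_normalizer(fit_normalizer(ds), ds)
  reports <- list(); rem_models <- list()
  y_pool <- integer(0); p_pool <- integer(0)
  for (f in sort(unique(fold))) {
    tr_idx <- which(fold != f); te_idx <- which(fold == f)
    d_tr <- subset_rows(ds, tr_idx)
    d_te <- subset_rows(ds, te_idx)
    if (!config$normalize_global) {
      ns <- fit_normalizer(d_tr)
      d_tr <- apply_normalizer(ns, d_tr)
      d_te <- apply_normalizer(ns, d_te)
    }
    if (any(d_tr$missing_mask) || any(d_te$missing_mask)) {
      rem <- rem_fit_transform(d_tr)
      d_tr <- rem$dataset
      d_te <- apply_imputer(rem$model, d_te)
      rem_models[[length(rem_models) + 1L]] <- rem$model
    }
    cfg <- config
    cfg$seed <- config$seed + f
    cfg$coarsening$seed <- cfg$seed
    cfg$refinement$seed <- cfg$seed
    m <- mlsvm_fit(d_tr, cfg)
    pred <- predict(m, d_te)
    reports[[f]] <- evaluate_predictions(d_te$labels, pred)
    y_pool <- c(y_pool, d_te$labels); p_pool <- c(p_pool, pred)
  }
  agg_of <- function(reps) {
    c(SN = mean(vapply(reps, `[[`, 0, "SN")),
      SP = mean(vapply(reps, `[[`, 0, "SP")),
      G_mean = mean(vapply(reps, `[[`, 0, "G_mean")),
      ACC = mean(vapply(reps, `[[`, 0, "ACC")))
  }
  pooled_rep <- evaluate_predictions(y_pool, p_pool)
  structure(list(folds = reports,
                 aggregate = if (pooled)
                   c(SN = pooled_rep$SN, SP = pooled_rep$SP,
                     G_mean = pooled_rep$G_mean, ACC = pooled_rep$ACC)
                 else agg_of(reports),
                 pooled = pooled_rep, rem_models = rem_models,
                 fold_id = fold, config = config),
            class = "mlsvm_cv_result")
}

#' @export
print.mlsvm_cv_result <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf(
    "mlsvm_cv_result (%d folds): SN %.4f  SP %.4f  G-mean %.4f  ACC %.4f\n",
    length(x$folds), a["SN"], a["SP"], a["G_mean"], a["ACC"]))
  invisible(x)
}
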