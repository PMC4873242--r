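#' Confusion matrix for binary -1/+1 labels
#'
#' +1 is the positive (minority) class: TP counts true +1 predicted +1,
#' TN true -1 predicted -1, FP predicted +1 but truly -1, FN the reverse.
#'
#' @param y_true,y_pred integer vectors in \{-1, +1\} of equal length.
#' @return A list of class `confusion_matrix` with `TP`, `FP`, `FN`, `TN`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (!all(c(y_true, y_pred) %in% c(-1L, 1L)))
    stop("labels must be -1/+1")
  structure(list(TP = sum(y_true == 1L & y_pred == 1L),
                 FP = sum(y_true == -1L & y_pred == 1L),
                 FN = sum(y_true == 1L & y_pred == -1L),
                 TN = sum(y_true == -1L & y_pred == -1L)),
            class = "confusion_matrix")
}

#' Performance measures from a confusion matrix
#'
#' Sensitivity `SN = TP / (TP + FN)`, specificity `SP = TN / (TN + FP)`,
#' `G-mean = sqrt(SN * SP)` and accuracy. The G-mean is the model-selection
#' objective throughout the package because it collapses to zero whenever
#' either class is entirely misclassified, which plain accuracy hides on
#' imbalanced data. An empty denominator (no positive or no negative
#' ground-truth samples) yields a rate of 0 with `degenerate = TRUE`,
#' deliberately penalizing degenerate predictors during tuning.
#'
#' @param cm a `confusion_matrix`, or TP count when the four counts are
#'   given separately.
#' @param FP,FN,TN optional counts when `cm` is numeric TP.
#' @return A list of class `metrics_report`: `SN`, `SP`, `G_mean`, `ACC`,
#'   `confusion`, `degenerate`.
#' @export
compute_metrics <- function(cm, FP = NULL, FN = NULL, TN = NULL) {
  if (!inherits(cm, "confusion_matrix")) {
    cm <- structure(list(TP = cm, FP = FP, FN = FN, TN = TN),
                    class = "confusion_matrix")
  }
  degenerate <- FALSE
  sn <- if (cm$TP + cm$FN > 0) cm$TP / (cm$TP + cm$FN) else {
    degenerate <- TRUE; 0
  }
  sp <- if (cm$TN + cm$FP > 0) cm$TN / (cm$TN + cm$FP) else {
    degenerate <- TRUE; 0
  }
  total <- cm$TP + cm$FP + cm$FN + cm$TN
  structure(list(SN = sn, SP = sp, G_mean = sqrt(sn * sp),
                 ACC = if (total > 0) (cm$TP + cm$TN) / total else 0,
                 confusion = cm, degenerate = degenerate),
            class = "metrics_report")
}

#' G-mean from sensitivity and specificity
#'
#' @param SN sensitivity in [0, 1].
#' @param SP specificity in [0, 1].
#' @return `sqrt(SN * SP)`.
#' @export
g_mean <- function(SN, SP) sqrt(SN * SP)

#' Performance measures of predictions against truth
#'
#' @param y_true,y_pred integer vectors in \{-1, +1\}.
#' @return A `metrics_report`.
#' @export
evaluate_predictions <- function(y_true, y_pred) {
  compute_metrics(confusion(y_true, y_pred))
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("SN = %.4f  SP = %.4f  G-mean = %.4f  ACC = %.4f\n",
              x$SN, x$SP, x$G_mean, x$ACC))
  cat(sprintf("  confusion: TP=%d FP=%d FN=%d TN=%d\n", x$confusion$TP,
              x$confusion$FP, x$confusion$FN, x$confusion$TN))
  invisible(x)
}
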