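#' Labeled dataset container
#'
#' Bundles a dense numeric feature matrix with integer class labels and a
#' logical missingness mask. Binary problems use labels in \{-1, +1\} with the
#' minority class mapped to +1 (the "positive" class), the convention followed
#' throughout the package: cost-sensitive weighting, sensitivity and G-mean
#' all treat +1 as the rare class of interest.
#'
#' @param features numeric matrix, one row per sample.
#' @param labels integer vector of class labels, one per row of `features`.
#'   Binary problems must use -1/+1.
#' @param missing_mask logical matrix of the same shape as `features`; `TRUE`
#'   marks an unobserved cell. Masked cells are set to `NA` in `features`.
#' @param feature_names optional character vector of column names.
#' @param class_map optional named vector recording the original class ids
#'   (names) against the recoded labels (values), kept for multiclass and
#'   for reporting.
#'
#' @return An object of class `labeled_dataset` with elements `features`,
#'   `labels`, `missing_mask`, `feature_names`, `class_map`.
#' @export
labeled_dataset <- function(features, labels, missing_mask = NULL,
                            feature_names = NULL, class_map = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  labels <- as.integer(labels)
  if (length(labels) != nrow(features))
    stop("label vector length must equal the number of samples")
  if (nrow(features) == 0L)
    stop("empty dataset: zero samples")
  if (is.null(missing_mask)) {
    missing_mask <- is.na(features)
  } else {
    missing_mask <- as.matrix(missing_mask)
    if (!identical(dim(missing_mask), dim(features)))
      stop("missing_mask shape must equal features shape")
    storage.mode(missing_mask) <- "logical"
  }
  features[missing_mask] <- NA_real_
  if (is.null(feature_names) && !is.null(colnames(features)))
    feature_names <- colnames(features)
  structure(
    list(features = features, labels = labels, missing_mask = missing_mask,
         feature_names = feature_names, class_map = class_map),
    class = "labeled_dataset"
  )
}

#' @export
print.labeled_dataset <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("labeled_dataset: %d samples x %d features\n",
              nrow(x$features), ncol(x$features)))
  cat("  classes:", paste(sprintf("%s (n=%d)", names(tab), tab),
                          collapse = ", "), "\n")
  n_mv <- sum(x$missing_mask)
  if (n_mv > 0)
    cat(sprintf("  missing cells: %d (%.1f%%)\n", n_mv,
                100 * n_mv / length(x$missing_mask)))
  invisible(x)
}

#' @export
dim.labeled_dataset <- function(x) dim(x$features)

n_samples <- function(d) nrow(d$features)
n_features <- function(d) ncol(d$features)

#' Subset a labeled dataset by row
#'
#' @param dataset a `labeled_dataset`.
#' @param idx integer row indices to keep.
#' @return A `labeled_dataset` restricted to the selected rows.
#' @export
subset_rows <- function(dataset, idx) {
  labeled_dataset(dataset$features[idx, , drop = FALSE],
                  dataset$labels[idx],
                  dataset$missing_mask[idx, , drop = FALSE],
                  feature_names = dataset$feature_names,
                  class_map = dataset$class_map)
}

# Remap arbitrary binary labels so the minority class is +1. Ties (equal
# class sizes) map the first level in sort order to +1.
remap_binary <- function(raw) {
  lev <- sort(unique(raw))
  if (length(lev) != 2L)
    stop("binary remapping requires exactly two classes, got ", length(lev))
  counts <- table(factor(raw, levels = lev))
  minority <- lev[which.min(counts)]
  labels <- ifelse(raw == minority, 1L, -1L)
  class_map <- stats::setNames(c(1L, -1L),
                               c(as.character(minority),
                                 as.character(lev[lev != minority])))
  list(labels = as.integer(labels), class_map = class_map)
}

#' Read a labeled dataset from CSV
#'
#' Expects a header row. The label column may be numeric or categorical; for
#' two-class data labels are recoded to \{-1, +1\} with the minority class as
#' +1 and the original ids kept in `class_map`. Feature cells equal to one of
#' `missing_tokens` (or empty) become missing-mask entries.
#'
#' @param path CSV file path.
#' @param label_column name of the label column.
#' @param missing_tokens character vector of cell values treated as missing.
#' @return A `labeled_dataset`.
#' @export
read_csv_dataset <- function(path, label_column = "label",
                             missing_tokens = c("", "NA", "NaN", "?")) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        na.strings = NULL)
  if (!label_column %in% names(df))
    stop("format error: label column '", label_column, "' not present")
  if (nrow(df) == 0L) stop("empty-input error: zero samples in ", path)
  raw_labels <- df[[label_column]]
  feat_df <- df[setdiff(names(df), label_column)]
  feat <- as.matrix(feat_df)
  mask <- matrix(feat %in% missing_tokens, nrow = nrow(feat))
  feat[mask] <- NA
  features <- matrix(suppressWarnings(as.numeric(feat)), nrow = nrow(feat),
                     dimnames = list(NULL, colnames(feat)))
  bad <- is.na(features) & !mask
  if (any(bad))
    stop("format error: non-numeric feature cells outside declared missing tokens")
  n_class <- length(unique(raw_labels))
  num_lab <- suppressWarnings(as.numeric(raw_labels))
  if (n_class == 2L && !anyNA(num_lab) &&
      all(sort(unique(num_lab)) == c(-1, 1))) {
    # already in the package's -1/+1 convention: keep as written
    labels <- as.integer(num_lab)
    class_map <- stats::setNames(c(1L, -1L), c("1", "-1"))
  } else if (n_class == 2L) {
    rm <- remap_binary(raw_labels)
    labels <- rm$labels; class_map <- rm$class_map
  } else {
    labels <- suppressWarnings(as.integer(as.numeric(raw_labels)))
    if (anyNA(labels)) labels <- as.integer(factor(raw_labels))
    class_map <- stats::setNames(unique(labels), unique(raw_labels))
  }
  labeled_dataset(features, labels, mask,
                  feature_names = colnames(feat), class_map = class_map)
}

#' Write a labeled dataset to CSV
#'
#' Missing cells are written as the literal token `NA` so that
#' [read_csv_dataset()] round-trips the mask.
#'
#' @param dataset a `labeled_dataset`.
#' @param path output path.
#' @param label_column name of the label column in the written file.
#' @export
write_csv_dataset <- function(dataset, path, label_column = "label") {
  feat <- dataset$features
  cn <- dataset$feature_names
  if (is.null(cn)) cn <- paste0("f", seq_len(ncol(feat)))
  df <- as.data.frame(feat)
  names(df) <- cn
  df[[label_column]] <- dataset$labels
  df <- df[c(label_column, cn)]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a dataset in LIBSVM/SVMlight sparse format
#'
#' Each line is `label index:value ...` with 1-based, strictly increasing
#' feature indices. Absent indices are zeros, not missing values: sparse
#' format carries no missingness, which enters only through explicit CSV
#' tokens.
#'
#' @param path file path.
#' @param n_features optional total feature count (otherwise the maximum
#'   index seen).
#' @return A `labeled_dataset` with an all-`FALSE` missing mask.
#' @export
read_libsvm <- function(path, n_features = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty-input error: no samples in ", path)
  parsed <- lapply(lines, function(ln) {
    tok <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    lab <- as.numeric(tok[1])
    if (is.na(lab)) stop("format error: bad label in line: ", ln)
    if (length(tok) == 1L)
      return(list(label = lab, idx = integer(0), val = numeric(0)))
    kv <- strsplit(tok[-1], ":", fixed = TRUE)
    idx <- as.integer(vapply(kv, `[`, "", 1L))
    val <- as.numeric(vapply(kv, `[`, "", 2L))
    if (anyNA(idx) || anyNA(val) || any(idx < 1L))
      stop("format error: bad index:value pair in line: ", ln)
    if (is.unsorted(idx, strictly = TRUE))
      stop("format error: non-increasing feature indices in line: ", ln)
    list(label = lab, idx = idx, val = val)
  })
  d <- if (is.null(n_features)) {
    mx <- suppressWarnings(max(0L, unlist(lapply(parsed, `[[`, "idx"))))
    max(mx, 1L)
  } else n_features
  X <- matrix(0, nrow = length(parsed), ncol = d)
  for (i in seq_along(parsed)) X[i, parsed[[i]]$idx] <- parsed[[i]]$val
  raw <- vapply(parsed, `[[`, 0, "label")
  if (length(unique(raw)) == 2L && !all(sort(unique(raw)) == c(-1, 1))) {
    rm <- remap_binary(raw)
    labeled_dataset(X, rm$labels, class_map = rm$class_map)
  } else {
    labeled_dataset(X, as.integer(raw))
  }
}

#' Write a dataset in LIBSVM/SVMlight sparse format
#'
#' Zero entries are omitted; indices are 1-based. Missing cells are not
#' representable in this format and raise an error.
#'
#' @param dataset a `labeled_dataset` with no missing values.
#' @param path output path.
#' @export
write_libsvm <- function(dataset, path) {
  if (any(dataset$missing_mask))
    stop("sparse format cannot encode missing values; impute first")
  X <- dataset$features
  lines <- vapply(seq_len(nrow(X)), function(i) {
    nz <- which(X[i, ] != 0)
    pairs <- if (length(nz)) paste0(nz, ":", format(X[i, nz], digits = 17,
                                                    trim = TRUE,
                                                    scientific = FALSE))
             else character(0)
    paste(c(dataset$labels[i], pairs), collapse = " ")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Per-feature standardization statistics
#'
#' Mean and standard deviation (sample, n-1 denominator) computed over the
#' observed entries of each feature only. Standard deviations are floored at
#' `floor` so constant features map to zero instead of dividing by zero.
#'
#' @param dataset a `labeled_dataset`.
#' @param floor lower bound for the standard deviation.
#' @return A list of class `normalization_stats` with `mean` and `std`.
#' @export
fit_normalizer <- function(dataset, floor = 1e-12) {
  X <- dataset$features
  mu <- apply(X, 2, mean, na.rm = TRUE)
  sd_ <- apply(X, 2, stats::sd, na.rm = TRUE)
  sd_[is.na(sd_)] <- 0
  if (any(sd_ < floor))
    warning("constant feature(s) detected; std floored, feature maps to 0")
  sd_ <- pmax(sd_, floor)
  structure(list(mean = mu, std = sd_), class = "normalization_stats")
}

#' Apply standardization statistics to a dataset
#'
#' @param stats a `normalization_stats` object from [fit_normalizer()].
#' @param dataset a `labeled_dataset`; its missing mask is unchanged.
#' @return The standardized `labeled_dataset`.
#' @export
apply_normalizer <- function(stats, dataset) {
  X <- sweep(sweep(dataset$features, 2, stats$mean, "-"), 2, stats$std, "/")
  labeled_dataset(X, dataset$labels, dataset$missing_mask,
                  feature_names = dataset$feature_names,
                  class_map = dataset$class_map)
}

#' Imbalance ratio of a two-class dataset
#'
#' The fraction of samples in the majority class, in [0.5, 1). A perfectly
#' balanced problem returns 0.5; a 98:2 split returns 0.98.
#'
#' @param dataset a `labeled_dataset` with two classes present.
#' @return Majority-class fraction.
#' @export
imbalance_ratio <- function(dataset) {
  tab <- table(dataset$labels)
  if (length(tab) != 2L)
    stop("undefined-ratio error: imbalance ratio needs exactly two classes")
  max(tab) / sum(tab)
}
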