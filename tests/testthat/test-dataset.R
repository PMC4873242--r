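test_that("CSV reader maps the minority class to +1 and tokens to the mask", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("label,x1,x2",
               "a,1.0,2.0",
               "a,2.0,NA",
               "a,3.0,4.0",
               "b,4.0,5.0"), f)
  ds <- read_csv_dataset(f)
  expect_equal(ds$labels, c(-1L, -1L, -1L, 1L))   # b is minority -> +1
  expect_equal(unname(ds$class_map["b"]), 1L)
  expect_equal(sum(ds$missing_mask), 1L)
  expect_true(ds$missing_mask[2, 2])
  expect_true(is.na(ds$features[2, 2]))
})

test_that("CSV reader rejects bad inputs", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("y,x", "1,2"), f)
  expect_error(read_csv_dataset(f, label_column = "label"), "label column")
  writeLines(c("label,x", "1,notanumber"), f)
  expect_error(read_csv_dataset(f), "non-numeric")
})

test_that("CSV write/read round-trips features, labels and mask", {
  set.seed(7)
  X <- matrix(round(rnorm(40), 6), 10, 4)
  ds <- labeled_dataset(X, rep(c(1L, -1L), 5))
  ds <- inject_missing(ds, 0.1, seed = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_csv_dataset(ds, f)
  back <- read_csv_dataset(f)
  expect_equal(back$features, ds$features, ignore_attr = TRUE)
  expect_equal(back$labels, ds$labels)
  expect_equal(unname(back$missing_mask), unname(ds$missing_mask))
})

test_that("LIBSVM format parses sparse rows with zeros for absent indices", {
  f <- withr::local_tempfile(fileext = ".libsvm")
  writeLines(c("+1 1:0.5 3:2.0", "-1 2:1.5", "-1"), f)
  ds <- read_libsvm(f)
  expect_equal(ds$features[1, ], c(0.5, 0, 2.0), ignore_attr = TRUE)
  expect_equal(ds$features[3, ], c(0, 0, 0), ignore_attr = TRUE)
  expect_equal(ds$labels, c(1L, -1L, -1L))
  expect_false(any(ds$missing_mask))
})

test_that("LIBSVM reader rejects non-increasing indices", {
  f <- withr::local_tempfile(fileext = ".libsvm")
  writeLines("+1 3:1.0 2:2.0", f)
  expect_error(read_libsvm(f), "non-increasing")
})

test_that("LIBSVM write/read round-trips a random sparse fixture", {
  set.seed(11)
  X <- matrix(rnorm(60), 12, 5)
  X[sample(60, 25)] <- 0
  ds <- labeled_dataset(X, rep(c(1L, -1L), 6))
  f <- withr::local_tempfile(fileext = ".libsvm")
  write_libsvm(ds, f)
  back <- read_libsvm(f, n_features = 5)
  expect_equal(back$features, ds$features, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$labels, ds$labels)
})

test_that("normalizer standardizes observed entries with sample std", {
  # two-point column: symmetric about 0, scaled by the sample std sqrt(2)
  ds <- labeled_dataset(cbind(c(1, 3)), c(1L, -1L))
  ns <- fit_normalizer(ds)
  out <- apply_normalizer(ns, ds)
  expect_equal(out$features[, 1], c(-1, 1) / sqrt(2), tolerance = 1e-12)

  x <- c(2, 4, 6, 8)
  ds2 <- labeled_dataset(cbind(x, c(0, 1, 0, 1)), c(1L, 1L, -1L, -1L))
  ns2 <- fit_normalizer(ds2)
  expect_equal(ns2$mean[1], 5, ignore_attr = TRUE)
  expect_equal(ns2$std[1], sd(x), ignore_attr = TRUE)
  out2 <- apply_normalizer(ns2, ds2)
  expect_equal(out2$features[, 1], (x - 5) / sd(x), ignore_attr = TRUE)
  expect_equal(mean(out2$features[, 1]), 0, tolerance = 1e-8)
  expect_equal(sd(out2$features[, 1]), 1, tolerance = 1e-8)

  # idempotence on already-standardized data
  out3 <- apply_normalizer(fit_normalizer(out2), out2)
  expect_equal(out3$features, out2$features, tolerance = 1e-8)
})

test_that("normalizer uses observed entries only and floors constants", {
  X <- cbind(c(1, 2, 3, 100), c(7, 7, 7, 7))
  M <- matrix(FALSE, 4, 2); M[4, 1] <- TRUE
  ds <- labeled_dataset(X, c(1L, 1L, -1L, -1L), M)
  expect_warning(ns <- fit_normalizer(ds), "constant")
  expect_equal(ns$mean[1], 2, ignore_attr = TRUE)  # 100 is masked
  out <- apply_normalizer(ns, ds)
  expect_equal(out$features[, 2], rep(0, 4), ignore_attr = TRUE)
  expect_equal(out$missing_mask, M, ignore_attr = TRUE)
})

test_that("fold-fitted normalizer never uses held-out statistics", {
  ds <- std_twonorm(100, d = 4, seed = 5)
  tr <- subset_rows(ds, 1:70)
  ns <- fit_normalizer(tr)
  ns_refit <- fit_normalizer(subset_rows(ds, 1:70))
  expect_identical(ns, ns_refit)
  expect_false(isTRUE(all.equal(ns$mean, fit_normalizer(ds)$mean)))
})

test_that("imbalance ratio matches printed benchmark class splits", {
  mk <- function(n_pos, n_neg) {
    n <- n_pos + n_neg
    labeled_dataset(cbind(seq_len(n)), rep(c(1L, -1L), c(n_pos, n_neg)))
  }
  expect_equal(round(imbalance_ratio(mk(9493, 571519)), 2), 0.98)
  expect_equal(round(imbalance_ratio(mk(4320, 8640)), 2), 0.67)
  expect_equal(imbalance_ratio(mk(50, 50)), 0.5)
  # invariant under label sign flip
  ds <- mk(30, 70)
  flipped <- labeled_dataset(ds$features, -ds$labels)
  expect_equal(imbalance_ratio(flipped), imbalance_ratio(ds))
  one <- labeled_dataset(cbind(1:5), rep(1L, 5))
  expect_error(imbalance_ratio(one), "two classes")
})
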