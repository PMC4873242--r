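test_that("RBF kernel matches its closed form", {
  x <- c(1, 2, 3)
  expect_equal(rbf_kernel(x, x, 2), 1)
  expect_equal(rbf_kernel(c(0, 0), c(3, 4), 0), 1)
  expect_equal(rbf_kernel(0, 1, log(2)), 0.5)
  expect_error(rbf_kernel(x, x, -1), "gamma")
  expect_error(rbf_kernel(c(1, 2), c(1, 2, 3), 1), "dimension")
  set.seed(1)
  A <- matrix(rnorm(12), 4, 3); B <- matrix(rnorm(6), 2, 3)
  K <- rbf_kernel(A, B, 0.3)
  expect_equal(K[2, 1], rbf_kernel(A[2, ], B[1, ], 0.3))
  expect_true(all(K > 0 & K <= 1))
})

test_that("two-point problem has the analytic midpoint boundary", {
  X <- rbind(c(0, 0), c(1, 0))
  y <- c(1L, -1L)
  m <- train_wsvm(X, weight_config(100, "uniform"), gamma = 0.01, y = y,
                  tolerance = 1e-8)
  expect_length(m$dual_coefs, 2L)             # both points support vectors
  expect_lt(abs(decision_value(m, c(0.5, 0))), 1e-6)
  expect_equal(predict(m, rbind(c(0.2, 0), c(0.8, 0))), c(1L, -1L))
})

test_that("dual solution satisfies the KKT-derived invariants", {
  set.seed(5)
  for (s in 1:3) {
    ds <- std_twonorm(60, d = 4, r_imb = 0.7, sep = 2, seed = s)
    y <- ds$labels
    w <- weight_config(3, "inverse-size", n_pos = sum(y == 1L),
                       n_neg = sum(y == -1L))
    m <- train_wsvm(ds, w, gamma = 0.4, tolerance = 1e-10)
    bound <- ifelse(y[m$support_indices] == 1L, w$C_plus, w$C_minus)
    expect_true(all(abs(m$dual_coefs) <= bound + 1e-8))
    expect_lt(abs(sum(m$dual_coefs)), 1e-8)
    expect_true(all(abs(m$dual_coefs) > 1e-8))
    # free support vectors sit on the margin: y * f(x) = 1
    f <- decision_value(m, ds$features[m$support_indices, ])
    free <- abs(m$dual_coefs) < bound - 1e-6
    if (any(free))
      expect_lt(max(abs(y[m$support_indices][free] * f[free] - 1)), 1e-6)
  }
})

test_that("libsvm dual objective matches an independent QP solve", {
  set.seed(42)
  n <- 20
  X <- matrix(rnorm(n * 3), n, 3)
  y <- rep(c(1L, -1L), c(7, 13))
  gamma <- 0.5
  w <- weight_config(2, "inverse-size", n_pos = 7, n_neg = 13)
  m <- train_wsvm(X, w, gamma = gamma, y = y, tolerance = 1e-10)
  obj_impl <- mlwsvm:::dual_objective(m)
  K <- rbf_kernel(X, X, gamma)
  H <- (y %*% t(y)) * K
  sol <- kernlab::ipop(c = rep(-1, n), H = H, A = t(y), b = 0, r = 0,
                       l = rep(0, n),
                       u = ifelse(y == 1L, w$C_plus, w$C_minus),
                       sigf = 12, maxiter = 100)
  a <- kernlab::primal(sol)
  obj_qp <- sum(a) - 0.5 * as.numeric(t(a) %*% H %*% a)
  expect_lt(abs(obj_impl - obj_qp), 1e-6)
})

test_that("uniform weighting coincides with the standard SVM", {
  ds <- std_twonorm(120, d = 5, r_imb = 0.7, sep = 2, seed = 8)
  m_w <- train_wsvm(ds, weight_config(2, "uniform"), gamma = 0.3,
                    tolerance = 1e-8)
  plain <- e1071::svm(ds$features, factor(ds$labels, levels = c(-1L, 1L)),
                      type = "C-classification", kernel = "radial",
                      gamma = 0.3, cost = 2, scale = FALSE,
                      tolerance = 1e-8)
  expect_setequal(m_w$support_indices, plain$index)
  grid <- ds$features[1:20, ]
  pr <- stats::predict(plain, grid, decision.values = TRUE)
  f_plain <- as.numeric(attr(pr, "decision.values")[, 1])
  f_ours <- decision_value(m_w, grid)
  # same decision function up to the backend's sign orientation
  expect_equal(abs(f_ours), abs(f_plain), tolerance = 1e-6)
  expect_equal(predict(m_w, grid), as.integer(as.character(pr)))
})

test_that("decision function ignores duplicated and non-support points", {
  ds <- std_twonorm(80, d = 4, sep = 3, seed = 10)
  m <- train_wsvm(ds, weight_config(1, "uniform"), gamma = 0.2,
                  tolerance = 1e-8)
  grid <- matrix(rnorm(40), 10, 4)
  # duplicating every training point leaves the decision function unchanged
  dup <- labeled_dataset(rbind(ds$features, ds$features),
                         c(ds$labels, ds$labels))
  m_dup <- train_wsvm(dup, weight_config(0.5, "uniform"), gamma = 0.2,
                      tolerance = 1e-8)
  expect_equal(decision_value(m_dup, grid), decision_value(m, grid),
               tolerance = 1e-4)
  # dropping non-support training points leaves predictions unchanged
  keep <- sort(m$support_indices)
  m_sv <- train_wsvm(ds$features[keep, ], weight_config(1, "uniform"),
                     gamma = 0.2, y = ds$labels[keep], tolerance = 1e-8)
  expect_equal(decision_value(m_sv, grid), decision_value(m, grid),
               tolerance = 1e-4)
  # row permutation invariance
  set.seed(1); perm <- sample(nrow(ds$features))
  m_p <- train_wsvm(ds$features[perm, ], weight_config(1, "uniform"),
                    gamma = 0.2, y = ds$labels[perm], tolerance = 1e-8)
  expect_equal(decision_value(m_p, grid), decision_value(m, grid),
               tolerance = 1e-6)
})

test_that("inverse-size weighting lifts minority G-mean on skewed overlap", {
  res <- vapply(1:10, function(s) {
    tr <- std_twonorm(600, d = 10, r_imb = 0.95, sep = 2, seed = s)
    te <- std_twonorm(600, d = 10, r_imb = 0.95, sep = 2, seed = s + 500)
    np <- sum(tr$labels == 1L); nn <- sum(tr$labels == -1L)
    mw <- train_wsvm(tr, weight_config(4, "inverse-size", n_pos = np,
                                       n_neg = nn), gamma = 0.1)
    mu <- train_wsvm(tr, weight_config(4, "uniform"), gamma = 0.1)
    c(w = evaluate_predictions(te$labels, predict(mw, te$features))$G_mean,
      u = evaluate_predictions(te$labels, predict(mu, te$features))$G_mean)
  }, c(w = 0, u = 0))
  expect_gt(median(res["w", ]), median(res["u", ]))
})

test_that("training rejects degenerate inputs", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(train_wsvm(X, y = rep(1L, 10)), "both classes")
  ds <- std_twonorm(20, d = 2, seed = 1)
  dm <- inject_missing(ds, 0.1, seed = 1)
  expect_error(train_wsvm(dm), "contract violation")
  expect_error(weight_config(-1), "positive")
})

test_that("models serialize to JSON and back without changing predictions", {
  ds <- std_twonorm(60, d = 3, seed = 2)
  m <- train_wsvm(ds, weight_config(1, "uniform"), gamma = 0.5)
  f <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, f)
  back <- read_model_json(f)
  grid <- matrix(rnorm(15), 5, 3)
  expect_equal(decision_value(back, grid), decision_value(m, grid),
               tolerance = 1e-10)
})
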