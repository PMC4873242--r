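test_that("training-set expansion obeys the neighbor cap", {
  ds <- std_twonorm(400, d = 6, seed = 3)
  h <- build_hierarchy(ds, coarsening_config(coarsest_bound = 100, seed = 3))
  expect_gte(length(h$levels), 2L)
  lv <- h$levels[[1]]
  S <- sort(c(lv$idx_pos[1:3], lv$idx_neg[1:3]))
  cfg0 <- refinement_config(neighbor_expansion = 0)
  expect_equal(build_training_set(lv, S, cfg0), S)
  cfg5 <- refinement_config(neighbor_expansion = 5)
  ts <- build_training_set(lv, S, cfg5)
  expect_true(all(S %in% ts))
  expect_lte(length(ts), length(S) * 6)
  expect_error(build_training_set(lv, integer(0), cfg5), "degenerate")
})

test_that("saturating expansion absorbs the whole level", {
  ds <- std_twonorm(40, d = 3, seed = 4)
  h <- build_hierarchy(ds, coarsening_config(coarsest_bound = 10, k = 39,
                                             seed = 4))
  lv <- h$levels[[1]]
  all_idx <- sort(c(lv$idx_pos, lv$idx_neg))
  cfg <- refinement_config(neighbor_expansion = 40L)
  ts <- build_training_set(lv, sort(c(lv$idx_pos[1], lv$idx_neg[1])), cfg)
  expect_equal(ts, all_idx)
})

test_that("cluster pairing reproduces the 10% nearest-opposite rule", {
  # 20 majority clusters, 5 minority clusters: a minority cluster is paired
  # with ceil(0.1 * 20) = 2 majority clusters; a majority cluster with
  # ceil(0.1 * 5) = 1 minority cluster
  set.seed(7)
  n <- 1000
  X <- matrix(rnorm(n * 4), n, 4)
  y <- rep(c(1L, -1L), c(200, 800))
  cfg <- refinement_config(Q_dt = 40L, opposite_fraction = 0.10, seed = 7)
  cp <- cluster_pairing(X, y, cfg)
  expect_equal(cp$K_pos, 5L)
  expect_equal(cp$K_neg, 20L)
  pos_deg <- table(factor(cp$pairs[, "pos"], levels = 1:5))
  expect_true(all(pos_deg >= 2))   # each minority cluster in >= 2 pairs
  neg_deg <- table(factor(cp$pairs[, "neg"], levels = 1:20))
  expect_true(all(neg_deg >= 1))   # every majority cluster is covered
  # fraction 1 pairs every cluster with every opposite cluster
  cfg_all <- refinement_config(Q_dt = 40L, opposite_fraction = 1, seed = 7)
  cp_all <- cluster_pairing(X, y, cfg_all)
  expect_equal(nrow(cp_all$pairs), cp_all$K_pos * cp_all$K_neg)
})

test_that("refine_level takes the direct branch below Q_dt", {
  ds <- std_twonorm(700, d = 6, r_imb = 0.7, sep = 3, seed = 5)
  h <- build_hierarchy(ds, coarsening_config(coarsest_bound = 200, seed = 5))
  r <- length(h$levels)
  lv_r <- h$levels[[r]]
  idx_r <- sort(c(lv_r$idx_pos, lv_r$idx_neg))
  coarse <- list(S = idx_r[1:30], C = 1, gamma = 0.1)
  cfg <- refinement_config(Q_dt = 10000L, neighbor_expansion = 3, seed = 5)
  sol <- refine_level(h, r - 2L, coarse, cfg)
  expect_equal(sol$trained_via, "direct")
  expect_s3_class(sol$model, "wsvm_model")
  expect_equal(sol$ud$n_evaluated, 13L)      # warm-started model selection
  expect_true(all(sol$S %in% build_training_set(h$levels[[r - 1L]],
                                                coarse$S, cfg)))
})

test_that("refine_level inherits parameters verbatim on the clustered branch", {
  ds <- std_twonorm(1200, d = 6, r_imb = 0.8, sep = 3, seed = 6)
  h <- build_hierarchy(ds, coarsening_config(coarsest_bound = 300, seed = 6))
  r <- length(h$levels)
  lv_r <- h$levels[[r]]
  idx_r <- sort(c(lv_r$idx_pos, lv_r$idx_neg))
  coarse <- list(S = idx_r, C = 2.5, gamma = 0.07)
  cfg <- refinement_config(Q_dt = 100L, neighbor_expansion = 5, seed = 6)
  sol <- refine_level(h, r - 2L, coarse, cfg)
  expect_equal(sol$trained_via, "clustered")
  expect_identical(sol$C, 2.5)
  expect_identical(sol$gamma, 0.07)
  # bookkeeping: support union is contained in the training set
  ts <- build_training_set(h$levels[[r - 1L]], coarse$S, cfg)
  expect_true(all(sol$S %in% ts))
  expect_gte(length(sol$S), 2L)
})

test_that("uncoarsening a single-level hierarchy is the identity", {
  ds <- std_twonorm(200, d = 5, seed = 7)
  h <- build_hierarchy(ds, coarsening_config(seed = 7))
  expect_length(h$levels, 1L)
  m <- train_wsvm(ds, weight_config(1, "uniform"), gamma = 0.2)
  coarse <- list(S = sort(m$support_indices), C = 1, gamma = 0.2, model = m)
  sol <- uncoarsen(h, coarse, refinement_config(seed = 7))
  expect_identical(sol$S, coarse$S)
  expect_identical(sol$model, m)
  expect_null(sol$log)
})

test_that("uncoarsening keeps support sets inside level training sets", {
  ds <- std_twonorm(1500, d = 8, r_imb = 0.8, sep = 3, seed = 8)
  h <- build_hierarchy(ds, coarsening_config(coarsest_bound = 250, seed = 8))
  r <- length(h$levels)
  lv_r <- h$levels[[r]]
  idx_r <- sort(c(lv_r$idx_pos, lv_r$idx_neg))
  Xr <- ds$features[idx_r, ]; yr <- ds$labels[idx_r]
  ud <- nested_ud_search(Xr, y = yr, seed = 8)
  w <- weight_config(ud$best_C, "inverse-size", n_pos = sum(yr == 1L),
                     n_neg = sum(yr == -1L))
  cm <- train_wsvm(Xr, w, gamma = ud$best_gamma, y = yr)
  sol <- uncoarsen(h, list(S = idx_r[cm$support_indices], C = ud$best_C,
                           gamma = ud$best_gamma, model = cm),
                   refinement_config(seed = 8))
  expect_s3_class(sol$model, "wsvm_model")
  expect_equal(nrow(sol$log), r - 1L)
  expect_true(all(sol$log$n_support <= sol$log$n_train))
})

test_that("multilevel refinement tracks a direct solve on small fixtures", {
  gm <- vapply(1:5, function(s) {
    tr <- std_twonorm(1200, d = 8, r_imb = 0.7, sep = 3, seed = s)
    te <- std_twonorm(600, d = 8, r_imb = 0.7, sep = 3, seed = s + 900)
    ml <- mlsvm_fit(tr, mlsvm_config(
      seed = s, coarsening = coarsening_config(coarsest_bound = 300,
                                               seed = s)))
    ud <- nested_ud_search(tr, seed = s)
    w <- weight_config(ud$best_C, "inverse-size",
                       n_pos = sum(tr$labels == 1L),
                       n_neg = sum(tr$labels == -1L))
    direct <- train_wsvm(tr, w, gamma = ud$best_gamma)
    c(ml = evaluate_predictions(te$labels, predict(ml, te))$G_mean,
      direct = evaluate_predictions(te$labels,
                                    predict(direct, te$features))$G_mean)
  }, c(ml = 0, direct = 0))
  expect_lte(median(gm["direct", ] - gm["ml", ]), 0.05)
})
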