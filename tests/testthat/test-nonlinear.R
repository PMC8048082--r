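test_that("a one-combination grid equals its direct CV evaluation", {
  p <- make_pipeline(n_rows = 150, seed = 73)
  g <- grid_search(p$Xsub, p$ysub, "knn",
                   list(n_neighbors = 5, weights = "uniform"),
                   cv_folds = 5, seed = 2)
  direct <- fit_user(p$Xsub, p$ysub, "knn",
                     list(n_neighbors = 5, weights = "uniform"),
                     cv_folds = 5, seed = 2)
  expect_equal(g$cv_accuracy, direct$cv_accuracy, tolerance = 1e-12)
  expect_equal(g$params$n_neighbors, 5)
})

test_that("grid search equals brute-force maximisation over a 2x2 grid", {
  p <- make_pipeline(n_rows = 150, seed = 79)
  grid <- list(n_neighbors = c(3, 9), weights = c("uniform", "distance"))
  g <- grid_search(p$Xsub, p$ysub, "knn", grid, cv_folds = 5, seed = 4)
  # exhaustive oracle: evaluate all 4 combinations directly
  combos <- expand.grid(grid, stringsAsFactors = FALSE)
  oracle <- vapply(seq_len(nrow(combos)), function(i) {
    fit_user(p$Xsub, p$ysub, "knn", as.list(combos[i, ]),
             cv_folds = 5, seed = 4)$cv_accuracy
  }, numeric(1))
  expect_equal(g$cv_accuracy, max(oracle), tolerance = 1e-12)
  expect_equal(nrow(g$cv_table), 4L)
  expect_equal(g$cv_table$cv_accuracy, oracle, tolerance = 1e-12)
  # ties break to the first combination in grid order
  first_max <- which.max(oracle)
  expect_equal(as.character(unlist(g$params[names(grid)])),
               as.character(unlist(combos[first_max, ])))
})

test_that("kNN neighbour grid beats spot-checked k values on two blobs", {
  ds <- two_blob_dataset(n = 120, seed = 5, gap = 4)
  X <- ds$descriptors; y <- ds$response
  g <- grid_search(X, y, "knn", list(n_neighbors = 1:50), cv_folds = 5,
                   seed = 6)
  for (k in c(1, 25, 50)) {
    spot <- fit_user(X, y, "knn", list(n_neighbors = k), cv_folds = 5,
                     seed = 6)$cv_accuracy
    expect_gte(g$cv_accuracy + 1e-9, spot)
  }
})

test_that("fit_user with the grid winner reproduces its predictions", {
  p <- make_pipeline(n_rows = 140, seed = 83)
  grid <- list(n_estimators = c(15, 30), max_depth = c(3, "None"))
  g <- grid_search(p$Xsub, p$ysub, "rf", grid, cv_folds = 3, seed = 5)
  u <- fit_user(p$Xsub, p$ysub, "rf", g$params, cv_folds = 3, seed = 5)
  vd <- p$feats[p$sets == "validation", ]
  expect_identical(predict_with_confidence(g, vd),
                   predict_with_confidence(u, vd))
})

test_that("user parameters default and echo correctly", {
  p <- make_pipeline(n_rows = 120, seed = 89)
  f <- fit_user(p$Xsub, p$ysub, "nb", cv_folds = 3, seed = 1)
  expect_equal(f$params$alpha, 1)          # learner default recorded
  expect_true(isTRUE(f$params$fit_prior))

  m <- fit_user(p$Xsub, p$ysub, "mlp",
                list(hidden_layer_sizes = "8,4", max_iter = 40),
                cv_folds = 3, seed = 1)
  expect_equal(m$params$hidden_layer_sizes, "8,4")
  expect_length(m$fit$W, 3L)               # two hidden layers + output
  expect_equal(ncol(m$fit$W[[1]]), 8L)
  expect_equal(ncol(m$fit$W[[2]]), 4L)
})

test_that("invalid learners, parameters and folds are rejected", {
  p <- make_pipeline(n_rows = 80, seed = 97)
  expect_error(fit_user(p$Xsub, p$ysub, "xgboost"), "unknown learner")
  expect_error(fit_user(p$Xsub, p$ysub, "knn", list(bogus = 1)),
               "invalid parameter")
  expect_error(grid_search(p$Xsub, p$ysub, "svc", list(bogus = 1)),
               "invalid parameter")
  n_sub <- nrow(p$Xsub)
  y_skew <- c(rep(1L, n_sub - 3L), rep(-1L, 3L))
  expect_error(fit_user(p$Xsub, y_skew, "knn", cv_folds = 5), "cv_folds")
})

test_that("every learner is seed-reproducible end to end", {
  p <- make_pipeline(n_rows = 120, seed = 101)
  quick <- list(knn = list(n_neighbors = 5),
                nb = list(alpha = 0.5),
                svc = list(C = 1, kernel = "linear"),
                rf = list(n_estimators = 10),
                gb = list(n_estimators = 10, subsample = 0.8),
                mlp = list(hidden_layer_sizes = 6, max_iter = 30))
  for (ln in names(quick)) {
    a <- fit_user(p$Xsub, p$ysub, ln, quick[[ln]], cv_folds = 3, seed = 7)
    b <- fit_user(p$Xsub, p$ysub, ln, quick[[ln]], cv_folds = 3, seed = 7)
    expect_equal(a$cv_accuracy, b$cv_accuracy, tolerance = 1e-12)
    expect_identical(predict_with_confidence(a, p$Xsub),
                     predict_with_confidence(b, p$Xsub))
  }
})

test_that("confidence thresholds drive the applicability-domain flag", {
  p <- make_pipeline(n_rows = 150, seed = 103)
  f <- fit_user(p$Xsub, p$ysub, "rf", list(n_estimators = 25), cv_folds = 3,
                seed = 2)
  pred0 <- predict_with_confidence(f, p$Xsub, confidence_threshold = 0)
  expect_true(all(pred0$in_ad))
  expect_true(all(pred0$confidence >= 0.5 - 1e-12))
  expect_error(predict_with_confidence(f, p$Xsub, confidence_threshold = 2),
               "confidence_threshold")

  # unanimous forest vote on a trivially separable point
  ds <- two_blob_dataset(n = 80, seed = 7, gap = 20)
  rf <- fit_user(ds$descriptors, ds$response, "rf",
                 list(n_estimators = 100), cv_folds = 3, seed = 3)
  pv <- predict_with_confidence(rf, ds$descriptors[1:2, , drop = FALSE])
  expect_equal(pv$confidence, c(1, 1))
})

test_that("high-confidence subsets are at least as accurate as the full set", {
  hits <- vapply(1:20, function(s) {
    p <- make_pipeline(n_rows = 150, n_descriptors = 4, seed = 200 + s,
                       effect_size = 0.6)
    f <- fit_user(p$Xsub, p$ysub, "nb", cv_folds = 3, seed = s)
    vd_idx <- which(p$sets == "validation")
    pv <- predict_with_confidence(f, p$feats[vd_idx, ], confidence_threshold = 0.7)
    truth <- p$ds$response[vd_idx]
    acc_all <- mean(pv$class == truth)
    if (!any(pv$in_ad)) return(TRUE)
    acc_in <- mean(pv$class[pv$in_ad] == truth[pv$in_ad])
    acc_in >= acc_all - 1e-12
  }, logical(1))
  expect_gte(sum(hits), 18L)
})

test_that("shipped default grid files parse to valid grids", {
  for (ln in c("knn", "nb", "svc", "rf", "gb", "mlp")) {
    path <- system.file("extdata", paste0("grid_", ln, ".csv"),
                        package = "mtqsarx")
    expect_true(nzchar(path))
    grid <- read_grid(path)
    expect_true(length(grid) >= 1)
    bad <- setdiff(names(grid), mtqsarx:::.LEARNERS[[ln]]$params)
    expect_length(bad, 0L)
  }
  grid <- read_grid(system.file("extdata", "grid_knn.csv", package = "mtqsarx"))
  expect_equal(grid$n_neighbors, 1:50)
  expect_equal(read_grid(system.file("extdata", "grid_rf.csv",
                                     package = "mtqsarx"))$max_depth[8], "None")
})
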