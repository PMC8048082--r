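test_that("pretreat removes low-variance then correlated columns, deterministically", {
  set.seed(1)
  x <- rnorm(50)
  X <- cbind(A = x, B = rep(2, 50), C = x + rnorm(50, sd = 0.12), D = rnorm(50))
  r_ac <- abs(cor(X[, "A"], X[, "C"]))
  expect_gt(r_ac, 0.95); expect_lt(r_ac, 0.999)   # fixture sanity

  out <- pretreat(X, variance_cutoff = 0.001, correlation_cutoff = 0.95)
  expect_equal(colnames(out$features), c("A", "D"))  # later column C dropped
  expect_equal(out$report$removed_constant, "B")
  expect_equal(out$report$removed_correlated$dropped, "C")
  expect_equal(out$report$removed_correlated$kept, "A")

  out2 <- pretreat(X, variance_cutoff = 0.001, correlation_cutoff = 0.999)
  expect_equal(colnames(out2$features), c("A", "C", "D"))  # both kept

  # exact duplicate at cutoff 1.0: exactly one of the pair removed
  X3 <- cbind(P = x, Q = x, R = rnorm(50))
  out3 <- pretreat(X3, variance_cutoff = 0, correlation_cutoff = 1.0)
  expect_equal(colnames(out3$features), c("P", "R"))

  expect_error(pretreat(cbind(K = rep(1, 10)), 0.001, 0.9), "every descriptor")
})

test_that("FS-LDA picks the planted descriptor first and logs monotone entries", {
  p <- make_pipeline(n_rows = 200, n_descriptors = 6, seed = 41)
  m <- fs_lda(p$Xsub, p$ysub, p_enter = 0.05, p_remove = 0.05,
              max_descriptors = 10)
  informative <- attr(p$ds, "informative")
  planted_cols <- as.vector(outer(paste0("d(", informative, ")"),
                                  names(p$ds$conditions),
                                  function(a, b) paste0(a, "_", b)))
  expect_true(m$selected[1] %in% planted_cols)
  # entry p-values never decrease down the selection log
  adds <- m$selection_log[m$selection_log$action == "add", ]
  expect_true(all(diff(adds$p_value) >= -1e-12))
  expect_lte(length(m$selected), 10L)
  expect_gte(m$wilks_lambda, 0); expect_lte(m$wilks_lambda, 1)
})

test_that("FS-LDA is deterministic and errors under the null", {
  p <- make_pipeline(n_rows = 150, seed = 43)
  m1 <- fs_lda(p$Xsub, p$ysub)
  m2 <- fs_lda(p$Xsub, p$ysub)
  expect_identical(m1$selected, m2$selected)
  expect_identical(m1$coefficients, m2$coefficients)

  # all-noise fixture (two candidate columns): no-model error expected in
  # >= 90% of 20 seeded replicates (~0.95^2 per replicate under the null)
  errors <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    Xn <- cbind(N1 = rnorm(200), N2 = rnorm(200))
    yn <- rep(c(1, -1), 100)
    inherits(tryCatch(fs_lda(Xn, yn, p_enter = 0.05), error = identity),
             "error")
  }, logical(1))
  expect_gte(sum(errors), 18L)
})

test_that("SFS-LDA selects the informative descriptor and beats the baseline", {
  p <- make_pipeline(n_rows = 200, n_descriptors = 4, seed = 47)
  m <- sfs_lda(p$Xsub, p$ysub, scoring = "accuracy", max_descriptors = 5,
               cv_folds = 5, seed = 3)
  informative <- attr(p$ds, "informative")
  planted_cols <- as.vector(outer(paste0("d(", informative, ")"),
                                  names(p$ds$conditions),
                                  function(a, b) paste0(a, "_", b)))
  expect_true(any(m$selected %in% planted_cols))
  maj <- max(mean(p$ysub == 1), mean(p$ysub == -1))
  expect_gt(m$cv_score, maj)

  # determinism under a fixed seed, for both scoring rules
  for (sc in c("accuracy", "auroc")) {
    a <- sfs_lda(p$Xsub, p$ysub, scoring = sc, seed = 9, max_descriptors = 3)
    b <- sfs_lda(p$Xsub, p$ysub, scoring = sc, seed = 9, max_descriptors = 3)
    expect_identical(a$selected, b$selected)
    expect_identical(a$cv_score, b$cv_score)
  }
})

test_that("SFS-LDA with max_descriptors = 1 matches the univariate CV oracle", {
  p <- make_pipeline(n_rows = 160, n_descriptors = 5, seed = 53)
  m <- sfs_lda(p$Xsub, p$ysub, max_descriptors = 1, cv_folds = 5, seed = 7)
  expect_length(m$selected, 1L)
  # exhaustive univariate oracle with the same fold assignment but its own
  # MASS::lda fits and accuracy computation
  fold <- mtqsarx:::.make_folds(p$ysub, 5, seed = 7)
  oracle <- vapply(colnames(p$Xsub), function(col) {
    mean(vapply(1:5, function(f) {
      tr <- fold != f
      fit <- MASS::lda(x = p$Xsub[tr, col, drop = FALSE],
                       grouping = factor(p$ysub[tr], levels = c(-1, 1)))
      pr <- predict(fit, p$Xsub[!tr, col, drop = FALSE])
      mean(as.integer(as.character(pr$class)) == p$ysub[!tr])
    }, numeric(1)))
  }, numeric(1))
  expect_equal(m$selected, names(oracle)[which.max(oracle)])
  expect_equal(m$cv_score, max(oracle), tolerance = 1e-12)
})

test_that("cv_folds larger than a class errors", {
  X <- cbind(A = rnorm(10))
  y <- c(rep(1, 7), rep(-1, 3))
  expect_error(sfs_lda(X, y, cv_folds = 4), "cv_folds")
})

test_that("wilks_lambda agrees with the variance-decomposition oracle", {
  # limits
  expect_equal(wilks_lambda(c(1, 2, 1, 2), c(1, 1, -1, -1))$lambda, 1)
  wl0 <- wilks_lambda(c(1, 1, 5, 5), c(1, 1, -1, -1))
  expect_equal(wl0$lambda, 0)
  expect_equal(wl0$p_value, 0)
  # {1,2} vs {3,4}: SSW = 0.5 + 0.5 = 1, SST = 5 -> lambda = 0.2
  scores <- c(1, 2, 3, 4); labels <- c(1, 1, -1, -1)
  ssw <- sum((c(1, 2) - 1.5)^2) + sum((c(3, 4) - 3.5)^2)
  sst <- sum((scores - mean(scores))^2)
  wl <- wilks_lambda(scores, labels)
  expect_equal(wl$lambda, ssw / sst)
  expect_equal(wl$lambda, 0.2)
  # F/p match a direct one-way ANOVA
  an <- anova(lm(scores ~ factor(labels)))
  expect_equal(wl$f_stat, an$`F value`[1])
  expect_equal(wl$p_value, an$`Pr(>F)`[1])
  expect_error(wilks_lambda(1:4, rep(1, 4)), "both classes")
})

test_that("lambda weakly decreases as informative descriptors are added", {
  p <- make_pipeline(n_rows = 200, seed = 59)
  m <- fs_lda(p$Xsub, p$ysub, max_descriptors = 4)
  lambdas <- vapply(seq_along(m$selected), function(k) {
    fit <- MASS::lda(x = p$Xsub[, m$selected[1:k], drop = FALSE],
                     grouping = factor(p$ysub, levels = c(-1, 1)))
    sc <- drop(p$Xsub[, m$selected[1:k], drop = FALSE] %*% fit$scaling[, 1])
    wilks_lambda(sc, p$ysub)$lambda
  }, numeric(1))
  expect_true(all(diff(lambdas) <= 1e-10))
})

test_that("the explicit linear rule reproduces the MASS::lda decision", {
  p <- make_pipeline(n_rows = 180, seed = 61)
  m <- fs_lda(p$Xsub, p$ysub)
  pr <- predict(m, p$Xsub)
  ref <- predict(m$lda, p$Xsub[, m$selected, drop = FALSE])
  expect_equal(pr$class, as.integer(as.character(ref$class)))
})

test_that("cross_correlation matches the pairwise formula oracle", {
  set.seed(5)
  X <- cbind(A = rnorm(30), B = rnorm(30), C = rnorm(30))
  cm <- cross_correlation(X)
  # brute-force Pearson r
  pearson <- function(a, b) {
    sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  }
  for (i in 1:3) for (j in 1:3) {
    expect_equal(cm[i, j], if (i == j) 1 else pearson(X[, i], X[, j]),
                 tolerance = 1e-12)
  }
  expect_equal(cm, t(cm))

  dup <- cbind(A = X[, 1], B = X[, 1])
  expect_equal(cross_correlation(dup)[1, 2], 1)

  orth <- cbind(A = c(1, -1, 1, -1), B = c(1, 1, -1, -1))
  expect_lt(abs(cross_correlation(orth)[1, 2]), 1e-10)

  expect_warning(cross_correlation(cbind(A = rep(1, 5), B = rnorm(5))),
                 "constant")
})

test_that("Y_c-randomisation separates a real model from chance", {
  p <- make_pipeline(n_rows = 250, seed = 67)
  m <- fs_lda(p$Xsub, p$ysub)
  expect_lte(m$wilks_lambda, 0.5)
  yc <- yc_randomize(p$training, m, method = 1, n_runs = 20, seed = 5,
                     subtrain_ids = p$sp$id[p$sp$set == "sub-training"])
  expect_equal(nrow(yc$table), 20L)
  expect_equal(yc$lambda_r, mean(yc$table$lambda, na.rm = TRUE))
  expect_gte(yc$lambda_r, 0.9)
  # reproducible
  yc2 <- yc_randomize(p$training, m, method = 1, n_runs = 1, seed = 11,
                      subtrain_ids = p$sp$id[p$sp$set == "sub-training"])
  yc3 <- yc_randomize(p$training, m, method = 1, n_runs = 1, seed = 11,
                      subtrain_ids = p$sp$id[p$sp$set == "sub-training"])
  expect_identical(yc2$table, yc3$table)
})

test_that("on pure noise the original and randomised lambdas agree", {
  p <- make_pipeline(n_rows = 200, seed = 71, effect_size = 0)
  # force a (meaningless) 2-descriptor model despite the null
  m <- fs_lda(p$Xsub, p$ysub, p_enter = 1, p_remove = 1, max_descriptors = 2)
  yc <- yc_randomize(p$training, m, method = 1, n_runs = 10, seed = 3,
                     subtrain_ids = p$sp$id[p$sp$set == "sub-training"])
  expect_lt(abs(yc$lambda_r - m$wilks_lambda), 0.1)
  expect_gt(yc$lambda_r, 0.9)
})
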