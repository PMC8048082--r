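test_that("element averages are the arithmetic mean over training actives", {
  ds <- tiny_train()
  bj <- fit_boxjenkins(ds, method = 1)
  # element e: active D1 values {1, 5} -> mean 2... wait, rows 1,2 are active
  expect_equal(unname(bj$avg$bt["e", "D1"]), mean(c(1, 5)))
  expect_equal(unname(bj$avg$bt["f", "D1"]), 3)   # single active row t5
  # ranges run over ALL training rows, both classes
  expect_equal(unname(bj$range[, "D1"]), c(0, 10))
})

test_that("Method 1 deviation is zero at the element active mean", {
  ds <- tiny_train()
  bj <- fit_boxjenkins(ds, method = 1)
  q <- mtqsar_dataset("q1", 1, data.frame(bt = "e"),
                      cbind(D1 = 3, D2 = 2))   # D1 = active mean of e
  expect_equal(unname(predict(bj, q)[, "d(D1)_bt"]), 0)
})

test_that("Method 3 matches the hand-computed operator value", {
  # element e: 2 actives of N = 5 -> p_c = 0.4; avg(D1|e) = 3; range = 10
  ds <- tiny_train()
  bj <- fit_boxjenkins(ds, method = 3)
  expect_equal(unname(bj$p_c$bt["e"]), 0.4)
  q <- mtqsar_dataset("q1", 1, data.frame(bt = "e"), cbind(D1 = 5, D2 = 2))
  # (5 - 3) / (10 * 0.4) = 0.5
  expect_equal(unname(predict(bj, q)[, "d(D1)_bt"]), 0.5)
})

test_that("Methods 2/3 drop invariant descriptors at fit time", {
  ds <- tiny_train()   # D2 is constant
  bj2 <- fit_boxjenkins(ds, method = 2)
  expect_equal(bj2$descriptors, "D1")
  expect_equal(bj2$dropped, "D2")
  expect_equal(colnames(predict(bj2, ds)), "d(D1)_bt")
  # Method 1 keeps it
  expect_true("D2" %in% fit_boxjenkins(ds, method = 1)$descriptors)
})

test_that("fit errors name zero-active elements and missing p_user", {
  ds <- mtqsar_dataset(paste0("r", 1:4), c(1, 1, -1, -1),
                       data.frame(bt = c("e", "e", "e", "f")),
                       cbind(D1 = 1:4))
  expect_error(fit_boxjenkins(ds, method = 1), "'bt'.*'f'")
  expect_error(fit_boxjenkins(ds, method = 4), "p_user")
})

test_that("unseen elements error by default and fall back on request", {
  ds <- tiny_train()
  bj <- fit_boxjenkins(ds, method = 1)
  q <- mtqsar_dataset("q1", 1, data.frame(bt = "ghost"), cbind(D1 = 1, D2 = 2))
  expect_error(predict(bj, q), "ghost")
  out <- predict(bj, q, unseen = "global-active-mean")
  expect_equal(unname(out[, "d(D1)_bt"]), 1 - mean(c(1, 5, 3)))
})

test_that("per-element active mean of Method 1 deviations is zero", {
  p <- make_pipeline(n_rows = 200, seed = 31)
  feats <- predict(p$bj, p$training)
  act <- p$training$response == 1L
  for (cc in names(p$training$conditions)) {
    for (e in unique(p$training$conditions[[cc]])) {
      rows <- act & p$training$conditions[[cc]] == e
      block <- feats[rows, grep(paste0("_", cc, "$"), colnames(feats)),
                     drop = FALSE]
      expect_lt(max(abs(colMeans(block))), 1e-10)
    }
  }
})

test_that("validation rows never leak into the fitted statistics", {
  ds <- generate_synthetic(synthetic_spec(n_rows = 150, n_descriptors = 4,
                                          condition_cardinalities = c(3, 2),
                                          seed = 13))
  sp <- split_random(ds, 0.3, seed = 1)
  train <- split_subset(ds, sp, "training")
  corrupted <- ds
  vd_rows <- match(sp$id[sp$set == "validation"], ds$ids)
  corrupted$descriptors[vd_rows, ] <- corrupted$descriptors[vd_rows, ] * 1e3 + 77
  train_after <- split_subset(corrupted, sp, "training")
  bj1 <- fit_boxjenkins(train, method = 2)
  bj2 <- fit_boxjenkins(train_after, method = 2)
  expect_identical(bj1$avg, bj2$avg)
  expect_identical(bj1$range, bj2$range)
  # and transforming the (uncorrupted) training rows is unchanged
  expect_identical(predict(bj1, train), predict(bj2, train))
})

test_that("Method 3 equals Method 2 divided by the element probability factor", {
  p2 <- make_pipeline(n_rows = 180, seed = 17, method = 2)
  bj3 <- fit_boxjenkins(p2$training, method = 3)
  f2 <- predict(p2$bj, p2$ds)
  f3 <- predict(bj3, p2$ds)
  for (cc in names(p2$ds$conditions)) {
    pc <- bj3$p_c[[cc]][p2$ds$conditions[[cc]]]
    cols <- grep(paste0("_", cc, "$"), colnames(f2))
    expect_equal(f3[, cols], f2[, cols] / pc, tolerance = 1e-12)
  }
})

test_that("feature count = retained descriptors x condition columns", {
  p <- make_pipeline(n_rows = 120, n_descriptors = 7, cards = c(4, 3, 2),
                     seed = 23)
  expect_equal(ncol(p$feats), 7L * 3L)
  expect_equal(nrow(p$feats), 120L)
  expect_true(all(is.finite(p$feats)))
})

test_that("Method 4 divides by the per-row user factor", {
  ds <- tiny_train()
  ds$p_user <- c(0.5, 0.5, 0.25, 1, 0.5)
  bj <- fit_boxjenkins(ds, method = 4)
  out <- predict(bj, ds)
  bj1 <- fit_boxjenkins(ds, method = 1)
  out1 <- predict(bj1, ds)
  expect_equal(out[, "d(D1)_bt"], out1[, "d(D1)_bt"] / ds$p_user)
  q <- mtqsar_dataset("q", 1, data.frame(bt = "e"), cbind(D1 = 4, D2 = 2))
  expect_error(predict(bj, q), "p_user")
})

test_that("probability factors match brute-force counting", {
  # 20-row fixture: two linked pairs + one unlinked column
  set.seed(42)
  n <- 20
  cond <- data.frame(me = sample(c("m1", "m2"), n, TRUE),
                     lc = sample(c("l1", "l2"), n, TRUE),
                     bs = sample(c("s1", "s2", "s3"), n, TRUE),
                     tm = sample(c("t1", "t2"), n, TRUE),
                     ag = sample(c("g1", "g2"), n, TRUE))
  ds <- mtqsar_dataset(paste0("r", 1:n), rep(c(1, -1), 10), cond,
                       cbind(D1 = rnorm(n)))
  links <- c(me = "lc", bs = "tm")
  p <- compute_probability_factors(ds, links)
  # independent brute-force oracle: explicit counts per row
  oracle <- vapply(seq_len(n), function(i) {
    f1 <- sum(cond$me == cond$me[i]) / sum(cond$lc == cond$lc[i])
    f2 <- sum(cond$bs == cond$bs[i]) / sum(cond$tm == cond$tm[i])
    f3 <- sum(cond$ag == cond$ag[i]) / n
    f1 * f2 * f3
  }, numeric(1))
  expect_equal(p, oracle, tolerance = 1e-12)

  # unlinked element with 5 of 50 rows -> 0.1
  n2 <- 50
  cond2 <- data.frame(ag = c(rep("g1", 5), rep("g2", 45)))
  ds2 <- mtqsar_dataset(paste0("q", 1:n2), rep(c(1, -1), 25), cond2,
                        cbind(D1 = rnorm(n2)))
  expect_equal(compute_probability_factors(ds2)[1], 0.1)

  # primary count equal to secondary count -> factor 1 for that pair
  cond3 <- data.frame(me = rep("m", 8), lc = rep("l", 8))
  ds3 <- mtqsar_dataset(paste0("w", 1:8), rep(c(1, -1), 4), cond3,
                        cbind(D1 = rnorm(8)))
  expect_equal(unique(compute_probability_factors(ds3, c(me = "lc"))), 1)

  # external element with zero training count errors
  ext <- mtqsar_dataset("x1", 1, data.frame(ag = "g9"), cbind(D1 = 0))
  expect_error(compute_probability_factors(ds2, newdata = ext), "g9")
})

test_that("avg_over = 'all' uses both classes in the element means", {
  ds <- tiny_train()
  bj <- fit_boxjenkins(ds, method = 1, avg_over = "all")
  expect_equal(unname(bj$avg$bt["e", "D1"]), mean(c(1, 5, 0)))
})
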