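# Minimal CART engine backing the random-forest and gradient-boosting
# learners. Axis-aligned binary splits chosen by exhaustive scan with
# cumulative-sum statistics; classification trees split on Gini or entropy
# of a 0/1 target, regression trees on squared error. Leaf values are the
# class-1 proportion (classification), the mean (regression) or a custom
# numerator/denominator ratio (used for the Newton leaf steps of boosting).
#
# Trees are grown depth-first on row-index vectors; randomness (feature
# subsampling) comes from the caller's RNG stream, so a seeded caller gets
# reproducible forests.

.tree_impurity <- function(cnt1, n, criterion) {
  p <- cnt1 / n
  if (criterion == "entropy") {
    h <- rep(0, length(p))
    ok <- p > 0 & p < 1
    h[ok] <- -(p[ok] * log2(p[ok]) + (1 - p[ok]) * log2(1 - p[ok]))
    h
  } else { # gini
    2 * p * (1 - p)
  }
}

.grow_tree <- function(X, y, idx, depth, control, leaf_num = NULL, leaf_den = NULL) {
  n <- length(idx)
  leaf_value <- function() {
    if (!is.null(leaf_num)) {
      den <- sum(leaf_den[idx])
      if (abs(den) < 1e-12) 0 else sum(leaf_num[idx]) / den
    } else {
      mean(y[idx])
    }
  }
  make_leaf <- function() list(leaf = TRUE, value = leaf_value(), n = n)

  if (n < control$min_samples_split || n < 2L * control$min_samples_leaf ||
      (!is.null(control$max_depth) && depth >= control$max_depth)) {
    return(make_leaf())
  }
  yv <- y[idx]
  if (control$task == "class" && (all(yv == yv[1L]))) return(make_leaf())
  if (control$task == "reg" && stats::var(yv) < 1e-14) return(make_leaf())

  p <- ncol(X)
  mtry <- min(control$mtry, p)
  feats <- if (mtry < p) sample.int(p, mtry) else seq_len(p)

  best <- list(gain = 0)
  msl <- control$min_samples_leaf
  for (f in feats) {
    x <- X[idx, f]
    o <- order(x)
    xs <- x[o]; ys <- yv[o]
    # splittable positions: value changes and both children large enough
    pos <- which(xs[-n] < xs[-1L])
    pos <- pos[pos >= msl & (n - pos) >= msl]
    if (!length(pos)) next
    if (control$task == "class") {
      cum1 <- cumsum(ys)
      nl <- pos; nr <- n - pos
      l1 <- cum1[pos]; r1 <- cum1[n] - l1
      imp <- (nl * .tree_impurity(l1, nl, control$criterion) +
                nr * .tree_impurity(r1, nr, control$criterion)) / n
      parent <- .tree_impurity(cum1[n], n, control$criterion)
    } else {
      cs <- cumsum(ys); cs2 <- cumsum(ys^2)
      nl <- pos; nr <- n - pos
      ssl <- cs2[pos] - cs[pos]^2 / nl
      ssr <- (cs2[n] - cs2[pos]) - (cs[n] - cs[pos])^2 / nr
      imp <- (ssl + ssr) / n
      parent <- (cs2[n] - cs[n]^2 / n) / n
    }
    gain <- parent - imp
    k <- which.max(gain)
    if (gain[k] > best$gain + 1e-12) {
      best <- list(gain = gain[k], feature = f,
                   threshold = (xs[pos[k]] + xs[pos[k] + 1L]) / 2)
    }
  }
  if (best$gain <= 0 || is.null(best$feature)) return(make_leaf())

  go_left <- X[idx, best$feature] <= best$threshold
  list(leaf = FALSE, feature = best$feature, threshold = best$threshold, n = n,
       left = .grow_tree(X, y, idx[go_left], depth + 1L, control, leaf_num, leaf_den),
       right = .grow_tree(X, y, idx[!go_left], depth + 1L, control, leaf_num, leaf_den))
}

.fit_tree <- function(X, y, task = c("class", "reg"), criterion = "gini",
                      max_depth = NULL, min_samples_split = 2L,
                      min_samples_leaf = 1L, mtry = ncol(X),
                      idx = seq_len(nrow(X)), leaf_num = NULL, leaf_den = NULL) {
  task <- match.arg(task)
  n <- length(idx)
  # sklearn-style fractional thresholds
  if (min_samples_split < 1) min_samples_split <- max(2L, ceiling(min_samples_split * n))
  if (min_samples_leaf < 1) min_samples_leaf <- max(1L, ceiling(min_samples_leaf * n))
  control <- list(task = task, criterion = criterion, max_depth = max_depth,
                  min_samples_split = as.integer(min_samples_split),
                  min_samples_leaf = as.integer(min_samples_leaf), mtry = mtry)
  .grow_tree(X, y, idx, 0L, control, leaf_num, leaf_den)
}

.predict_tree <- function(node, X) {
  out <- numeric(nrow(X))
  recurse <- function(nd, rows) {
    if (!length(rows)) return()
    if (nd$leaf) {
      out[rows] <<- nd$value
      return()
    }
    left <- X[rows, nd$feature] <= nd$threshold
    recurse(nd$left, rows[left])
    recurse(nd$right, rows[!left])
  }
  recurse(node, seq_len(nrow(X)))
  out
}

.resolve_mtry <- function(max_features, p, default_all = FALSE) {
  if (is.null(max_features) || identical(max_features, "None")) return(p)
  if (is.character(max_features)) {
    switch(tolower(max_features),
           auto = if (default_all) p else max(1L, floor(sqrt(p))),
           sqrt = max(1L, floor(sqrt(p))),
           log2 = max(1L, floor(log2(p))),
           stop("unknown max_features value '", max_features, "'", call. = FALSE))
  } else {
    mf <- as.numeric(max_features)
    if (mf < 1) max(1L, floor(mf * p)) else min(p, as.integer(mf))
  }
}
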