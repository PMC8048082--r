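# The six non-linear learners. Each has an internal fit function returning
# a classed object with a .learner_prob() method giving the probability (or
# vote fraction) of the positive class. Labels arrive as +1/-1; internally
# classifiers work with a 0/1 copy. All stochastic learners draw from the
# caller-seeded RNG stream.

# ---- k-nearest neighbours ---------------------------------------------------

.fit_knn <- function(X, y, params) {
  p <- .merge_params(list(n_neighbors = 5, weights = "uniform",
                          algorithm = "auto"), params, "knn")
  k <- as.integer(p$n_neighbors)
  if (k < 1 || k > nrow(X)) stop("n_neighbors must lie in [1, n]", call. = FALSE)
  if (!p$weights %in% c("uniform", "distance")) {
    stop("knn weights must be 'uniform' or 'distance'", call. = FALSE)
  }
  if (!p$algorithm %in% c("auto", "ball_tree", "kd_tree", "brute")) {
    stop("unknown knn algorithm '", p$algorithm, "'", call. = FALSE)
  }
  structure(list(X = X, y01 = as.integer(y == 1L), params = p), class = "mtq_knn")
}

.prob_knn <- function(fit, X) {
  k <- as.integer(fit$params$n_neighbors)
  nn <- FNN::get.knnx(fit$X, X, k = k)
  prob <- numeric(nrow(X))
  for (i in seq_len(nrow(X))) {
    lab <- fit$y01[nn$nn.index[i, ]]
    if (fit$params$weights == "uniform") {
      prob[i] <- mean(lab)
    } else {
      d <- nn$nn.dist[i, ]
      if (any(d == 0)) {
        prob[i] <- mean(lab[d == 0])
      } else {
        w <- 1 / d
        prob[i] <- sum(w * lab) / sum(w)
      }
    }
  }
  prob
}

# ---- Bernoulli naive Bayes --------------------------------------------------

.fit_nb <- function(X, y, params) {
  p <- .merge_params(list(alpha = 1, fit_prior = TRUE, binarize = 0), params, "nb")
  alpha <- as.numeric(p$alpha)
  if (alpha < 0) stop("nb alpha must be >= 0", call. = FALSE)
  B <- (X > as.numeric(p$binarize)) * 1
  y01 <- as.integer(y == 1L)
  n1 <- sum(y01); n0 <- sum(1 - y01)
  theta1 <- (colSums(B[y01 == 1L, , drop = FALSE]) + alpha) / (n1 + 2 * alpha)
  theta0 <- (colSums(B[y01 == 0L, , drop = FALSE]) + alpha) / (n0 + 2 * alpha)
  fit_prior <- isTRUE(p$fit_prior) || identical(p$fit_prior, "True")
  prior1 <- if (fit_prior) n1 / (n1 + n0) else 0.5
  structure(list(theta1 = theta1, theta0 = theta0, prior1 = prior1,
                 binarize = as.numeric(p$binarize), params = p),
            class = "mtq_nb")
}

.prob_nb <- function(fit, X) {
  B <- (X > fit$binarize) * 1
  ll1 <- B %*% log(fit$theta1) + (1 - B) %*% log(1 - fit$theta1) + log(fit$prior1)
  ll0 <- B %*% log(fit$theta0) + (1 - B) %*% log(1 - fit$theta0) + log(1 - fit$prior1)
  drop(1 / (1 + exp(ll0 - ll1)))
}

# ---- support vector classifier (dual QP via quadprog) -----------------------

.svc_kernel <- function(A, B, p) {
  switch(p$kernel,
         linear = A %*% t(B),
         rbf = {
           d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
           exp(-p$gamma * pmax(d2, 0))
         },
         poly = (p$gamma * A %*% t(B) + p$coef0)^p$degree,
         sigmoid = tanh(p$gamma * A %*% t(B) + p$coef0),
         stop("unknown svc kernel '", p$kernel, "'", call. = FALSE))
}

.fit_svc <- function(X, y, params) {
  p <- .merge_params(list(C = 1, kernel = "rbf", gamma = "scale", degree = 3,
                          coef0 = 0), params, "svc")
  p$kernel <- tolower(p$kernel)
  if (!p$kernel %in% c("linear", "rbf", "poly", "sigmoid")) {
    stop("unknown svc kernel '", p$kernel, "'", call. = FALSE)
  }
  if (identical(p$gamma, "scale")) {
    p$gamma <- 1 / (ncol(X) * max(stats::var(as.vector(X)), 1e-12))
  }
  p$gamma <- as.numeric(p$gamma); p$C <- as.numeric(p$C)
  p$degree <- as.numeric(p$degree); p$coef0 <- as.numeric(p$coef0)
  if (p$C <= 0) stop("svc C must be > 0", call. = FALSE)
  yv <- as.numeric(y)
  n <- nrow(X)
  K <- .svc_kernel(X, X, p)
  Q <- (yv %o% yv) * K
  Q <- Q + diag(1e-8 * max(diag(Q), 1), n)   # PD ridge for the QP solver
  sol <- quadprog::solve.QP(
    Dmat = Q, dvec = rep(1, n),
    Amat = cbind(yv, diag(n), -diag(n)),
    bvec = c(0, rep(0, n), rep(-p$C, n)), meq = 1)
  alpha <- pmin(pmax(sol$solution, 0), p$C)
  sv <- alpha > 1e-8
  margin <- alpha > 1e-8 & alpha < p$C - 1e-8
  if (!any(sv)) { sv <- rep(TRUE, n); margin <- sv }
  coef <- alpha[sv] * yv[sv]
  Ksv <- K[, sv, drop = FALSE]
  b_rows <- if (any(margin)) which(margin) else which(sv)
  b <- mean(yv[b_rows] - Ksv[b_rows, , drop = FALSE] %*% coef)
  fit <- structure(list(sv_x = X[sv, , drop = FALSE], coef = coef, b = b,
                        params = p), class = "mtq_svc")
  # Platt scaling on the training decision values for confidence estimates
  dec <- .svc_decision(fit, X)
  platt <- tryCatch(
    suppressWarnings(stats::glm((y == 1L) ~ dec, family = stats::binomial())),
    error = function(e) NULL)
  fit$platt <- if (!is.null(platt) && all(is.finite(coef(platt)))) coef(platt)
  fit
}

.svc_decision <- function(fit, X) {
  drop(.svc_kernel(X, fit$sv_x, fit$params) %*% fit$coef) + fit$b
}

.prob_svc <- function(fit, X) {
  dec <- .svc_decision(fit, X)
  if (!is.null(fit$platt)) {
    pr <- stats::plogis(fit$platt[1L] + fit$platt[2L] * dec)
    # keep the hard decision and the probability consistent at the boundary
    pr[dec > 0 & pr < 0.5] <- 0.5
    pr[dec <= 0 & pr >= 0.5] <- 0.5 - 1e-9
    pr
  } else {
    stats::plogis(dec)
  }
}

# ---- random forest ----------------------------------------------------------

.fit_rf <- function(X, y, params) {
  p <- .merge_params(list(n_estimators = 100, criterion = "gini",
                          max_depth = NULL, max_features = "auto",
                          min_samples_leaf = 1, min_samples_split = 2,
                          bootstrap = TRUE), params, "rf")
  p$criterion <- tolower(as.character(p$criterion))
  if (!p$criterion %in% c("gini", "entropy")) {
    stop("rf criterion must be 'gini' or 'entropy'", call. = FALSE)
  }
  if (identical(p$max_depth, "None")) p$max_depth <- NULL
  ntree <- as.integer(p$n_estimators)
  if (ntree < 1) stop("n_estimators must be >= 1", call. = FALSE)
  boot <- isTRUE(p$bootstrap) || identical(p$bootstrap, "True")
  mtry <- .resolve_mtry(p$max_features, ncol(X))
  y01 <- as.integer(y == 1L)
  n <- nrow(X)
  trees <- lapply(seq_len(ntree), function(b) {
    idx <- if (boot) sample.int(n, n, replace = TRUE) else seq_len(n)
    .fit_tree(X, y01, task = "class", criterion = p$criterion,
              max_depth = if (!is.null(p$max_depth)) as.integer(p$max_depth),
              min_samples_split = as.numeric(p$min_samples_split),
              min_samples_leaf = as.numeric(p$min_samples_leaf),
              mtry = mtry, idx = idx)
  })
  structure(list(trees = trees, params = p), class = "mtq_rf")
}

.prob_rf <- function(fit, X) {
  votes <- vapply(fit$trees, function(tr) .predict_tree(tr, X) > 0.5,
                  logical(nrow(X)))
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = 1L)
  rowMeans(votes)   # fraction of trees voting +1
}

# ---- gradient boosting ------------------------------------------------------

.fit_gb <- function(X, y, params) {
  p <- .merge_params(list(loss = "deviance", learning_rate = 0.1,
                          n_estimators = 100, subsample = 1,
                          min_samples_split = 2, min_samples_leaf = 1,
                          max_depth = 3, max_features = NULL,
                          criterion = "friedman_mse"), params, "gb")
  p$loss <- tolower(as.character(p$loss))
  if (!p$loss %in% c("deviance", "exponential")) {
    stop("gb loss must be 'deviance' or 'exponential'", call. = FALSE)
  }
  lr <- as.numeric(p$learning_rate)
  sub <- as.numeric(p$subsample)
  if (lr <= 0 || sub <= 0 || sub > 1) stop("invalid gb learning_rate/subsample", call. = FALSE)
  ntree <- as.integer(p$n_estimators)
  mtry <- .resolve_mtry(p$max_features, ncol(X), default_all = TRUE)
  y01 <- as.integer(y == 1L)
  ypm <- ifelse(y01 == 1L, 1, -1)
  n <- nrow(X)
  pbar <- mean(y01)
  pbar <- min(max(pbar, 1e-6), 1 - 1e-6)
  f0 <- if (p$loss == "deviance") log(pbar / (1 - pbar)) else 0.5 * log(pbar / (1 - pbar))
  Fv <- rep(f0, n)
  trees <- vector("list", ntree)
  for (b in seq_len(ntree)) {
    if (p$loss == "deviance") {
      prob <- stats::plogis(Fv)
      resid <- y01 - prob
      den <- pmax(prob * (1 - prob), 1e-12)
    } else {
      w <- exp(-ypm * Fv)
      resid <- ypm * w
      den <- pmax(w, 1e-12)
    }
    idx <- if (sub < 1) sample.int(n, max(2L, floor(sub * n))) else seq_len(n)
    tr <- .fit_tree(X, resid, task = "reg",
                    max_depth = as.integer(p$max_depth),
                    min_samples_split = as.numeric(p$min_samples_split),
                    min_samples_leaf = as.numeric(p$min_samples_leaf),
                    mtry = mtry, idx = idx, leaf_num = resid, leaf_den = den)
    Fv <- Fv + lr * .predict_tree(tr, X)
    trees[[b]] <- tr
  }
  structure(list(trees = trees, f0 = f0, params = p, lr = lr), class = "mtq_gb")
}

.gb_score <- function(fit, X) {
  Fv <- rep(fit$f0, nrow(X))
  for (tr in fit$trees) Fv <- Fv + fit$lr * .predict_tree(tr, X)
  Fv
}

.prob_gb <- function(fit, X) {
  Fv <- .gb_score(fit, X)
  if (fit$params$loss == "deviance") stats::plogis(Fv) else stats::plogis(2 * Fv)
}

# ---- multilayer perceptron --------------------------------------------------

.mlp_act <- function(z, act) {
  switch(act, identity = z, logistic = stats::plogis(z), tanh = tanh(z),
         relu = pmax(z, 0), stop("unknown mlp activation '", act, "'", call. = FALSE))
}
.mlp_dact <- function(a, act) {
  switch(act, identity = 1 + 0 * a, logistic = a * (1 - a), tanh = 1 - a^2,
         relu = (a > 0) * 1)
}

.fit_mlp <- function(X, y, params) {
  p <- .merge_params(list(hidden_layer_sizes = 100, activation = "relu",
                          solver = "adam", alpha = 1e-4,
                          learning_rate = "constant",
                          learning_rate_init = 0.001, max_iter = 200),
                     params, "mlp")
  hidden <- as.integer(unlist(strsplit(as.character(
    paste(p$hidden_layer_sizes, collapse = ",")), "[,;x ]+")))
  hidden <- hidden[!is.na(hidden) & hidden > 0]
  if (!length(hidden)) stop("mlp hidden_layer_sizes must give >= 1 unit", call. = FALSE)
  p$activation <- tolower(as.character(p$activation))
  p$solver <- tolower(as.character(p$solver))
  p$learning_rate <- tolower(as.character(p$learning_rate))
  if (!p$activation %in% c("identity", "logistic", "tanh", "relu")) {
    stop("unknown mlp activation '", p$activation, "'", call. = FALSE)
  }
  if (!p$solver %in% c("sgd", "adam")) stop("mlp solver must be 'sgd' or 'adam'", call. = FALSE)
  if (!p$learning_rate %in% c("constant", "adaptive", "invscaling")) {
    stop("unknown mlp learning_rate schedule '", p$learning_rate, "'", call. = FALSE)
  }
  y01 <- as.numeric(y == 1L)
  sizes <- c(ncol(X), hidden, 1L)
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {  # Glorot-style initialisation from the caller's RNG
    lim <- sqrt(6 / (sizes[l] + sizes[l + 1L]))
    W[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1L], -lim, lim),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- rep(0, sizes[l + 1L])
  }
  n <- nrow(X)
  alpha <- as.numeric(p$alpha)
  lr0 <- as.numeric(p$learning_rate_init)
  lr <- lr0
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(x) x * 0); vb <- mb
  velW <- mW; velb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  best_loss <- Inf; stall <- 0L
  for (it in seq_len(as.integer(p$max_iter))) {
    A <- vector("list", L + 1L); A[[1L]] <- X
    for (l in seq_len(L)) {
      Z <- sweep(A[[l]] %*% W[[l]], 2L, b[[l]], "+")
      A[[l + 1L]] <- if (l < L) .mlp_act(Z, p$activation) else stats::plogis(Z)
    }
    out <- drop(A[[L + 1L]])
    out <- pmin(pmax(out, 1e-12), 1 - 1e-12)
    loss <- -mean(y01 * log(out) + (1 - y01) * log(1 - out)) +
      0.5 * alpha * sum(vapply(W, function(w) sum(w^2), numeric(1))) / n
    delta <- matrix((out - y01) / n, ncol = 1L)
    for (l in rev(seq_len(L))) {
      gW <- t(A[[l]]) %*% delta + alpha * W[[l]] / n
      gb <- colSums(delta)
      if (l > 1L) {
        delta <- (delta %*% t(W[[l]])) * .mlp_dact(A[[l]], p$activation)
      }
      if (p$solver == "adam") {
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        mhW <- mW[[l]] / (1 - beta1^it); vhW <- vW[[l]] / (1 - beta2^it)
        mhb <- mb[[l]] / (1 - beta1^it); vhb <- vb[[l]] / (1 - beta2^it)
        W[[l]] <- W[[l]] - lr * mhW / (sqrt(vhW) + eps)
        b[[l]] <- b[[l]] - lr * mhb / (sqrt(vhb) + eps)
      } else {
        step_lr <- if (p$learning_rate == "invscaling") lr0 / it^0.5 else lr
        velW[[l]] <- 0.9 * velW[[l]] - step_lr * gW
        velb[[l]] <- 0.9 * velb[[l]] - step_lr * gb
        W[[l]] <- W[[l]] + velW[[l]]
        b[[l]] <- b[[l]] + velb[[l]]
      }
    }
    if (loss < best_loss - 1e-6) { best_loss <- loss; stall <- 0L } else stall <- stall + 1L
    if (p$learning_rate == "adaptive" && stall >= 10L) { lr <- lr / 5; stall <- 0L }
  }
  structure(list(W = W, b = b, params = p, activation = p$activation),
            class = "mtq_mlp")
}

.prob_mlp <- function(fit, X) {
  A <- X
  L <- length(fit$W)
  for (l in seq_len(L)) {
    Z <- sweep(A %*% fit$W[[l]], 2L, fit$b[[l]], "+")
    A <- if (l < L) .mlp_act(Z, fit$activation) else stats::plogis(Z)
  }
  drop(A)
}
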