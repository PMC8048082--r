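# Linear discriminant modelling on deviation descriptors. The two-group
# discriminant is solved by MASS::lda (SVD-based, priors from sub-training
# class frequencies); stepwise entry p-values come from ordinary least
# squares on the +1/-1 class indicator, where the coefficient t-test
# coincides with the partial-F test for a single entering variable.

.lda_fit <- function(X, y) {
  suppressWarnings(MASS::lda(x = X, grouping = factor(y, levels = c(-1, 1))))
}

# reduce a fitted 2-class MASS::lda to an explicit linear rule:
# predict +1  <=>  x %*% coefficients + intercept > 0
.lda_linear <- function(fit) {
  S <- fit$scaling[, 1L]
  g <- drop(fit$means %*% S)            # projected group centroids, names "-1","1"
  gpos <- g[["1"]]; gneg <- g[["-1"]]
  prior <- fit$prior
  if (gpos == gneg) {
    return(list(coefficients = S * 0, intercept = 0))
  }
  m <- (gpos + gneg) / 2 - log(prior[["1"]] / prior[["-1"]]) / (gpos - gneg)
  s <- sign(gpos - gneg)
  list(coefficients = S * s, intercept = -m * s)
}

.lda_decision <- function(model, features) {
  X <- features[, model$selected, drop = FALSE]
  drop(X %*% model$coefficients) + model$intercept
}

#' Wilks' lambda of discriminant scores
#'
#' `lambda = SS_within / SS_total` of the scores across the two groups:
#' 0 means perfect discrimination, 1 none. `F` and its p-value come from
#' the standard one-way decomposition (`df = (1, n - 2)` for two groups).
#'
#' @param scores numeric discriminant scores.
#' @param labels group labels (two distinct values required).
#' @return list with `lambda`, `f_stat`, `p_value`.
#' @export
wilks_lambda <- function(scores, labels) {
  labels <- as.character(labels)
  groups <- unique(labels)
  if (length(groups) < 2L) stop("both classes must be present", call. = FALSE)
  n <- length(scores)
  gm <- mean(scores)
  sst <- sum((scores - gm)^2)
  ssw <- sum(unlist(lapply(groups, function(g) {
    s <- scores[labels == g]
    sum((s - mean(s))^2)
  })))
  if (sst == 0) return(list(lambda = 1, f_stat = 0, p_value = 1))
  lambda <- ssw / sst
  k <- length(groups)
  if (lambda == 0) {
    return(list(lambda = 0, f_stat = Inf, p_value = 0))
  }
  f_stat <- ((sst - ssw) / (k - 1)) / (ssw / (n - k))
  list(lambda = lambda, f_stat = f_stat,
       p_value = stats::pf(f_stat, k - 1, n - k, lower.tail = FALSE))
}

.finish_lda <- function(X, y, selected, selection_log, selector, params) {
  fit <- .lda_fit(X[, selected, drop = FALSE], y)
  lin <- .lda_linear(fit)
  model <- structure(
    list(selected = selected, coefficients = lin$coefficients,
         intercept = lin$intercept, lda = fit, selector = selector,
         params = params, selection_log = selection_log),
    class = "mtqsar_lda")
  scores <- .lda_decision(model, X)
  wl <- wilks_lambda(scores, y)
  model$wilks_lambda <- wl$lambda
  model$f_stat <- wl$f_stat
  model$p_value <- wl$p_value
  model
}

#' Fast stepwise (FS) LDA feature selection
#'
#' Classic p-value driven stepwise selection: at each forward step every
#' remaining candidate is added in turn to an ordinary-least-squares
#' regression of the +1/-1 class indicator on the current descriptors; the
#' candidate with the lowest coefficient p-value enters if it beats
#' `p_enter`. After every entry, any included descriptor whose p-value in
#' the joint fit exceeds `p_remove` is eliminated. Selection stops when no
#' candidate qualifies or `max_descriptors` is reached; the final
#' discriminant is then fitted on the selected set. Ties on p-values break
#' towards the lower stored column index, so the procedure is fully
#' deterministic.
#'
#' @param features numeric matrix of (pre-treated) deviation descriptors of
#'   the sub-training set.
#' @param labels sub-training responses in `{+1, -1}`.
#' @param p_enter p-value to enter (default 0.05).
#' @param p_remove p-value to remove (default 0.05). A warning is emitted
#'   when `p_enter > p_remove` (entry looser than removal).
#' @param max_descriptors maximum model size (default 10).
#' @return an object of class `mtqsar_lda`: selected descriptor names (in
#'   entry order), explicit linear rule (`coefficients`, `intercept`; the
#'   prediction is `+1` iff `x'coef + intercept > 0`), the underlying
#'   `MASS::lda` fit, Wilks' `lambda`/`F`/`p` on the sub-training
#'   discriminant scores, and a `selection_log` data.frame.
#' @export
fs_lda <- function(features, labels, p_enter = 0.05, p_remove = 0.05,
                   max_descriptors = 10) {
  stopifnot(is.matrix(features), max_descriptors >= 1)
  y <- .validate_response(labels, nrow(features))
  if (p_enter > p_remove) {
    warning("p_enter > p_remove: descriptors may enter only to be removed immediately")
  }
  yv <- as.numeric(y)
  cols <- colnames(features)
  selected <- character(0)
  log_rows <- list()

  ols_p <- function(current) {
    # p-values of each descriptor's coefficient in the joint OLS fit of the
    # +1/-1 indicator; aliased (collinear) terms come back NA
    Xm <- features[, current, drop = FALSE]
    fit <- stats::lm(yv ~ Xm)
    ct <- summary(fit)$coefficients
    p <- stats::setNames(rep(NA_real_, length(current)), current)
    # summary() drops aliased (collinear) terms; coef() keeps them as NA in
    # the original order, which lets us map p-values back by position
    full <- stats::coef(fit)[-1L]
    p[!is.na(full)] <- ct[-1L, 4L]
    p
  }
  coef_p <- function(current, cand) {
    p <- ols_p(c(current, cand))
    unname(p[cand])
  }
  included_p <- function(current) ols_p(current)

  step <- 0L
  repeat {
    if (length(selected) >= max_descriptors) break
    candidates <- setdiff(cols, selected)
    if (!length(candidates)) break
    pvals <- vapply(candidates, function(cand) coef_p(selected, cand), numeric(1))
    if (all(is.na(pvals))) break
    best <- which.min(pvals)   # first minimum = lowest column index on ties
    if (is.na(pvals[best]) || pvals[best] >= p_enter) break
    selected <- c(selected, candidates[best])
    step <- step + 1L
    log_rows[[length(log_rows) + 1L]] <-
      data.frame(step = step, action = "add", descriptor = candidates[best],
                 p_value = unname(pvals[best]), stringsAsFactors = FALSE)
    # backward elimination
    repeat {
      if (length(selected) < 2L) break
      ip <- included_p(selected)
      worst <- which.max(ip)
      if (is.na(ip[worst]) || ip[worst] <= p_remove) break
      out <- selected[worst]
      selected <- setdiff(selected, out)
      step <- step + 1L
      log_rows[[length(log_rows) + 1L]] <-
        data.frame(step = step, action = "remove", descriptor = out,
                   p_value = unname(ip[worst]), stringsAsFactors = FALSE)
    }
  }
  if (!length(selected)) {
    stop("no model: no descriptor meets p_enter = ", p_enter, call. = FALSE)
  }
  .finish_lda(features, y, selected, do.call(rbind, log_rows), "fs",
              list(p_enter = p_enter, p_remove = p_remove,
                   max_descriptors = max_descriptors))
}

# stratified fold assignment, seeded and deterministic
.make_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  set.seed(seed)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    if (length(idx) < k) {
      stop("cv_folds (", k, ") exceeds the size of class ", cl,
           " (", length(idx), ")", call. = FALSE)
    }
    fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# cross-validated score of an LDA on a candidate column set
.cv_lda_score <- function(X, y, cols, fold, scoring) {
  k <- max(fold)
  sc <- vapply(seq_len(k), function(f) {
    tr <- fold != f
    fit <- tryCatch(.lda_fit(X[tr, cols, drop = FALSE], y[tr]),
                    error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    pr <- stats::predict(fit, X[!tr, cols, drop = FALSE])
    if (scoring == "accuracy") {
      mean(as.integer(as.character(pr$class)) == y[!tr])
    } else {
      if (length(unique(y[!tr])) < 2L) return(NA_real_)
      roc_auroc(pr$posterior[, "1"], y[!tr])$auroc
    }
  }, numeric(1))
  if (all(is.na(sc))) -Inf else mean(sc, na.rm = TRUE)
}

#' Sequential forward (floating) selection LDA
#'
#' Greedy forward selection maximising the cross-validated performance of a
#' two-group discriminant: starting from the empty set, the candidate whose
#' addition gives the best CV score is added while it strictly improves on
#' the current best; with `floating = TRUE`, after each addition the
#' procedure attempts conditional exclusions of earlier descriptors that
#' improve the score further. Stops at no improvement or at
#' `max_descriptors`. Fold assignment is stratified by class and seeded, so
#' repeated runs yield the same model.
#'
#' @inheritParams fs_lda
#' @param scoring `"accuracy"` (fraction correctly classified) or
#'   `"auroc"` (area under the ROC of the posterior for class `+1`),
#'   averaged over folds.
#' @param floating enable conditional exclusion steps (default `TRUE`).
#' @param cv_folds number of stratified folds (default 5, >= 2).
#' @param seed integer seed for the fold assignment.
#' @return an `mtqsar_lda` (see [fs_lda()]); `selection_log` records each
#'   add/remove with its CV score.
#' @export
sfs_lda <- function(features, labels, scoring = c("accuracy", "auroc"),
                    floating = TRUE, max_descriptors = 10, cv_folds = 5,
                    seed = 1) {
  stopifnot(is.matrix(features), max_descriptors >= 1)
  scoring <- match.arg(scoring)
  if (cv_folds < 2) stop("cv_folds must be >= 2", call. = FALSE)
  y <- .validate_response(labels, nrow(features))
  fold <- .make_folds(y, cv_folds, seed)
  cols <- colnames(features)

  selected <- character(0)
  best <- -Inf
  log_rows <- list()
  step <- 0L
  repeat {
    if (length(selected) >= max_descriptors) break
    candidates <- setdiff(cols, selected)
    if (!length(candidates)) break
    sc <- vapply(candidates, function(cand)
      .cv_lda_score(features, y, c(selected, cand), fold, scoring), numeric(1))
    iadd <- which.max(sc)
    if (!is.finite(sc[iadd]) || sc[iadd] <= best) break
    selected <- c(selected, candidates[iadd])
    best <- unname(sc[iadd])
    step <- step + 1L
    log_rows[[length(log_rows) + 1L]] <-
      data.frame(step = step, action = "add", descriptor = candidates[iadd],
                 cv_score = best, stringsAsFactors = FALSE)
    if (floating && length(selected) > 2L) {
      repeat {
        removable <- utils::head(selected, -1L)   # never the one just added
        sc_rm <- vapply(removable, function(d)
          .cv_lda_score(features, y, setdiff(selected, d), fold, scoring),
          numeric(1))
        irm <- which.max(sc_rm)
        if (!length(sc_rm) || !is.finite(sc_rm[irm]) || sc_rm[irm] <= best) break
        out <- removable[irm]
        selected <- setdiff(selected, out)
        best <- unname(sc_rm[irm])
        step <- step + 1L
        log_rows[[length(log_rows) + 1L]] <-
          data.frame(step = step, action = "remove", descriptor = out,
                     cv_score = best, stringsAsFactors = FALSE)
        if (length(selected) <= 2L) break
      }
    }
  }
  if (!length(selected)) {
    stop("no model: no descriptor improves the cross-validated score", call. = FALSE)
  }
  model <- .finish_lda(features, y, selected, do.call(rbind, log_rows), "sfs",
                       list(scoring = scoring, floating = floating,
                            max_descriptors = max_descriptors,
                            cv_folds = cv_folds, seed = seed))
  model$cv_score <- best
  model
}

#' @export
print.mtqsar_lda <- function(x, ...) {
  cat("LDA model (", toupper(x$selector), " selection): ",
      length(x$selected), " descriptor(s)\n", sep = "")
  cat("  ", paste(x$selected, collapse = ", "), "\n", sep = "")
  cat(sprintf("  Wilks' lambda = %.4f, F = %.2f, p = %.3g\n",
              x$wilks_lambda, x$f_stat, x$p_value))
  invisible(x)
}

#' Predict with a fitted mt-QSAR LDA model
#'
#' @param object an `mtqsar_lda` from [fs_lda()] or [sfs_lda()].
#' @param features deviation-descriptor matrix containing the selected
#'   columns.
#' @param ... unused.
#' @return data.frame with `score` (signed discriminant decision value;
#'   positive means class `+1`) and `class` (`+1`/`-1`).
#' @export
predict.mtqsar_lda <- function(object, features, ...) {
  d <- .lda_decision(object, features)
  data.frame(score = d, class = ifelse(d > 0, 1L, -1L))
}

#' Serialise an LDA model to a coefficient table
#' @param model an `mtqsar_lda`.
#' @return data.frame of descriptor/coefficient rows plus the intercept and
#'   goodness-of-fit statistics, suitable for [write_report()].
#' @export
lda_report <- function(model) {
  stopifnot(inherits(model, "mtqsar_lda"))
  rbind(
    data.frame(term = model$selected, value = unname(model$coefficients)),
    data.frame(term = c("(intercept)", "wilks_lambda", "F", "p"),
               value = c(model$intercept, model$wilks_lambda, model$f_stat,
                         model$p_value))
  )
}
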