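#' Confusion matrix for +1/-1 classification
#'
#' The `+1` class is the positive class throughout: TP counts rows that are
#' truly `+1` and predicted `+1`, TN rows truly `-1` predicted `-1`.
#'
#' @param truth true labels in `{+1, -1}`.
#' @param predicted predicted labels in `{+1, -1}`.
#' @return a list of class `confusion_matrix` with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_matrix <- function(truth, predicted) {
  n <- length(truth)
  truth <- .validate_response(truth, n)
  predicted <- .validate_response(predicted, n, column = "predicted")
  structure(list(
    TP = sum(truth == 1L & predicted == 1L),
    TN = sum(truth == -1L & predicted == -1L),
    FP = sum(truth == -1L & predicted == 1L),
    FN = sum(truth == 1L & predicted == -1L)
  ), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("TP =", x$TP, " TN =", x$TN, " FP =", x$FP, " FN =", x$FN, "\n")
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Computes sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy
#' `(TP+TN)/total`, F1 score `2TP/(2TP+FP+FN)` and the Matthews correlation
#' coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' Sensitivity, specificity, accuracy and F1 are returned in percent at
#' full precision (reports round to 2 decimals); MCC lies in `[-1, 1]`.
#' A zero denominator makes the corresponding metric `NA` ("undefined"),
#' never silently 0.
#'
#' @param cm a [confusion_matrix()], or a list/vector with elements
#'   `TP`, `TN`, `FP`, `FN`.
#' @return named list: `TP`, `TN`, `FP`, `FN`, `sensitivity`, `specificity`,
#'   `accuracy`, `f1` (percent), `mcc`.
#' @examples
#' m <- classification_metrics(list(TP = 110, TN = 36, FP = 8, FN = 6))
#' round(m$accuracy, 2)  # 91.25
#' @export
classification_metrics <- function(cm) {
  cm <- as.list(cm)
  tp <- as.numeric(cm$TP); tn <- as.numeric(cm$TN)
  fp <- as.numeric(cm$FP); fn <- as.numeric(cm$FN)
  if (anyNA(c(tp, tn, fp, fn)) || any(c(tp, tn, fp, fn) < 0)) {
    stop("confusion matrix needs non-negative TP, TN, FP, FN", call. = FALSE)
  }
  total <- tp + tn + fp + fn
  if (total < 1) stop("empty confusion matrix", call. = FALSE)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  mcc_den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  list(
    TP = tp, TN = tn, FP = fp, FN = fn,
    sensitivity = 100 * ratio(tp, tp + fn),
    specificity = 100 * ratio(tn, tn + fp),
    accuracy = 100 * (tp + tn) / total,
    f1 = 100 * ratio(2 * tp, 2 * tp + fp + fn),
    mcc = if (mcc_den == 0) NA_real_ else (tp * tn - fp * fn) / mcc_den
  )
}

#' ROC curve and AUROC by threshold sweep
#'
#' Sweeps the decision threshold over the distinct score values (ties share
#' a threshold), emitting one (FPR, TPR) point per threshold plus the (0,0)
#' and (1,1) anchors; the area is integrated by the trapezoid rule, which
#' makes it equal to the Mann-Whitney pair-counting statistic with ties
#' counted one half.
#'
#' @param scores numeric scores, larger = more `+1`-like.
#' @param labels true labels in `{+1, -1}`; both classes required.
#' @return list with `roc` (data.frame `threshold`, `fpr`, `tpr`, ordered by
#'   decreasing threshold) and `auroc`.
#' @export
roc_auroc <- function(scores, labels) {
  labels <- .validate_response(labels, length(scores))
  pos <- labels == 1L
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present", call. = FALSE)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores[pos] >= t) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores[!pos] >= t) / n_neg, numeric(1))
  roc <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  if (roc$fpr[nrow(roc)] < 1 || roc$tpr[nrow(roc)] < 1) {
    roc <- rbind(roc, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  }
  auroc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
  list(roc = roc, auroc = auroc)
}

#' Applicability domain by the standardisation approach
#'
#' For every query row each feature is standardised against the sub-training
#' mean and standard deviation, `S_k = |x_k - mu_k| / sigma_k`. The
#' three-branch rule then flags outliers: if `max_k S_k <= 3` the row is
#' inside the domain; if `min_k S_k > 3` it is an outlier; otherwise the
#' auxiliary score `S_new = mean_k(S_k) + 1.28 * sd_k(S_k)` decides
#' (outlier iff `S_new > 3`). Features with zero sub-training SD cannot be
#' standardised and are skipped with a warning.
#'
#' @param subtrain numeric matrix of sub-training features (the statistics
#'   basis).
#' @param query numeric matrix with the same columns; defaults to
#'   `subtrain` (self-assessment).
#' @return a data.frame of class `ad_report` with per-row `max_s`, `min_s`,
#'   `s_new` (NA when not needed by the rule), `in_ad` (logical) and the
#'   query row names as `id`; attribute `n_outliers`.
#' @export
ad_standardization <- function(subtrain, query = subtrain) {
  stopifnot(is.matrix(subtrain), is.matrix(query))
  if (!identical(colnames(subtrain), colnames(query))) {
    stop("feature mismatch between sub-training and query matrices", call. = FALSE)
  }
  mu <- colMeans(subtrain)
  sigma <- apply(subtrain, 2L, stats::sd)
  usable <- sigma > 0
  if (!any(usable)) stop("every feature has zero sub-training SD", call. = FALSE)
  if (!all(usable)) {
    warning("skipping zero-SD feature(s): ",
            paste(colnames(subtrain)[!usable], collapse = ", "))
  }
  S <- abs(sweep(query[, usable, drop = FALSE], 2L, mu[usable], "-"))
  S <- sweep(S, 2L, sigma[usable], "/")
  max_s <- apply(S, 1L, max)
  min_s <- apply(S, 1L, min)
  s_new <- rep(NA_real_, nrow(S))
  in_ad <- rep(NA, nrow(S))
  in_ad[max_s <= 3] <- TRUE
  in_ad[min_s > 3] <- FALSE
  mid <- which(is.na(in_ad))
  if (length(mid)) {
    s_new[mid] <- apply(S[mid, , drop = FALSE], 1L, function(s) {
      mean(s) + 1.28 * stats::sd(s)
    })
    in_ad[mid] <- s_new[mid] <= 3
  }
  out <- data.frame(
    id = if (!is.null(rownames(query))) rownames(query) else as.character(seq_len(nrow(query))),
    max_s = max_s, min_s = min_s, s_new = s_new, in_ad = in_ad,
    stringsAsFactors = FALSE)
  attr(out, "n_outliers") <- sum(!in_ad)
  class(out) <- c("ad_report", "data.frame")
  out
}

#' Condition-wise prediction report
#'
#' Groups predictions by the full experimental condition tuple within each
#' of the test and validation sets and reports, per tuple, the instance
#' count and the percent accuracy (2 decimals). Tuples absent from a set
#' get `NA` in both cells (written as `"na"` by [write_report()]). Tuples
#' that are poorly predicted (0% accuracy in some set) or supported by a
#' negligible number of cases (`count <= min_count` in every set where they
#' occur) are flagged.
#'
#' @param predicted predicted labels in `{+1, -1}`.
#' @param truth true labels in `{+1, -1}`.
#' @param conditions data.frame of condition columns, one row per
#'   prediction.
#' @param sets character vector assigning each row to `"test"` or
#'   `"validation"`.
#' @param min_count flag threshold for the negligible-cases screen
#'   (default 3).
#' @return a data.frame of class `condition_wise_report`: the condition
#'   columns, then `test_n`, `test_accuracy`, `validation_n`,
#'   `validation_accuracy`, `flagged`.
#' @export
condition_wise <- function(predicted, truth, conditions, sets, min_count = 3) {
  n <- length(truth)
  truth <- .validate_response(truth, n)
  predicted <- .validate_response(predicted, n, column = "predicted")
  if (!is.data.frame(conditions)) conditions <- as.data.frame(conditions)
  if (nrow(conditions) != n || length(sets) != n) {
    stop("predicted, truth, conditions and sets must align row-wise", call. = FALSE)
  }
  bad <- setdiff(unique(sets), c("test", "validation"))
  if (length(bad)) stop("sets must be 'test' or 'validation' (got '", bad[1L], "')", call. = FALSE)

  key <- do.call(paste, c(conditions, sep = "\r"))
  tuples <- unique(key)
  correct <- predicted == truth
  cell <- function(tup, s) {
    rows <- key == tup & sets == s
    if (!any(rows)) return(c(NA_real_, NA_real_))
    c(sum(rows), round(100 * mean(correct[rows]), 2))
  }
  rows <- lapply(tuples, function(tup) {
    ts <- cell(tup, "test"); vd <- cell(tup, "validation")
    data.frame(conditions[match(tup, key), , drop = FALSE],
               test_n = ts[1L], test_accuracy = ts[2L],
               validation_n = vd[1L], validation_accuracy = vd[2L],
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  accs <- cbind(out$test_accuracy, out$validation_accuracy)
  ns <- cbind(out$test_n, out$validation_n)
  out$flagged <- apply(accs, 1L, function(a) any(a == 0, na.rm = TRUE)) |
    apply(ns, 1L, function(k) all(is.na(k) | k <= min_count))
  class(out) <- c("condition_wise_report", "data.frame")
  out
}

#' Full per-set classification report
#'
#' Evaluates scores and predicted labels per set (sub-training, test,
#' validation) into confusion-matrix counts, the metric block of
#' [classification_metrics()] and the AUROC of [roc_auroc()].
#'
#' @param truth true labels in `{+1, -1}`.
#' @param predicted predicted labels in `{+1, -1}`.
#' @param scores numeric decision scores (larger = more positive), or
#'   `NULL` to skip ROC/AUROC.
#' @param sets character vector of set labels per row.
#' @return a data.frame of class `classification_report`, one row per set
#'   with columns `set`, `n`, `TP`, `TN`, `FP`, `FN`, `sensitivity`,
#'   `specificity`, `accuracy`, `f1`, `mcc`, `auroc` (percentages rounded
#'   to 2 decimals, mcc/auroc to 3); the per-set ROC curves are kept in
#'   attribute `roc`.
#' @export
classification_report <- function(truth, predicted, scores = NULL, sets) {
  n <- length(truth)
  stopifnot(length(predicted) == n, length(sets) == n)
  set_names <- intersect(c("sub-training", "test", "validation"), unique(sets))
  set_names <- c(set_names, setdiff(unique(sets), set_names))
  rocs <- list()
  rows <- lapply(set_names, function(s) {
    i <- sets == s
    m <- classification_metrics(confusion_matrix(truth[i], predicted[i]))
    auroc <- NA_real_
    if (!is.null(scores) && length(unique(truth[i])) == 2L) {
      ra <- roc_auroc(scores[i], truth[i])
      rocs[[s]] <<- ra$roc
      auroc <- ra$auroc
    }
    data.frame(set = s, n = sum(i), TP = m$TP, TN = m$TN, FP = m$FP, FN = m$FN,
               sensitivity = round(m$sensitivity, 2),
               specificity = round(m$specificity, 2),
               accuracy = round(m$accuracy, 2), f1 = round(m$f1, 2),
               mcc = round(m$mcc, 3), auroc = round(auroc, 3),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "roc") <- rocs
  class(out) <- c("classification_report", "data.frame")
  out
}

#' Write ROC points to CSV (and optionally a PNG)
#'
#' @param roc data.frame from [roc_auroc()] (`threshold`, `fpr`, `tpr`).
#' @param path output CSV path.
#' @param png_path optional path for a plain ROC plot.
#' @return invisibly, the ROC data.frame.
#' @export
write_roc <- function(roc, path, png_path = NULL) {
  utils::write.csv(roc, path, row.names = FALSE, quote = FALSE)
  if (!is.null(png_path)) {
    grDevices::png(png_path, width = 600, height = 600)
    on.exit(grDevices::dev.off())
    plot(roc$fpr, roc$tpr, type = "l", xlab = "False positive rate",
         ylab = "True positive rate", main = "ROC")
    abline(0, 1, lty = 2)
  }
  invisible(roc)
}
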