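#' Y_c-randomisation of a linear mt-QSAR model
#'
#' Y-randomisation extended to condition-dependent descriptors: per run, the
#' response column *and* every condition column of the training data are
#' scrambled (each column is permuted across rows, independently of the
#' others — the stronger null), the Box-Jenkins model is refitted on the
#' scrambled data, the model's own deviation descriptors are recomputed, and
#' a discriminant using the SAME descriptor names is refitted on the
#' scrambled sub-training rows. The per-run Wilks' lambda and sub-training
#' accuracy are recorded; a robust original model should have a lambda far
#' below the randomised mean `lambda_r` (which approaches 1) and an accuracy
#' well above `accuracy_r` (which approaches the majority-class rate).
#'
#' Scrambling can leave a condition element with zero actives; such elements
#' fall back to the global active mean (see [fit_boxjenkins()]), so runs
#' never abort on sparse elements. A run whose discriminant is degenerate
#' (e.g. a constant recomputed descriptor) is recorded as `NA` and excluded
#' from the means.
#'
#' @param train an [mtqsar_dataset()] of training rows (the rows the
#'   Box-Jenkins statistics are fitted on).
#' @param model the original `mtqsar_lda` whose descriptor names are refitted.
#' @param method Box-Jenkins operator id (1-4) used for the original model.
#' @param n_runs number of randomised runs (>= 1; 100 is conventional).
#' @param seed integer seed; the whole report is reproducible from it.
#' @param subtrain_ids ids of the sub-training rows the discriminant is
#'   fitted and scored on; defaults to all training rows.
#' @param avg_over passed to [fit_boxjenkins()].
#' @return an object of class `yc_report`: `n_runs`, `lambda_r` and
#'   `accuracy_r` (means over non-degenerate runs; accuracy in percent) and
#'   the per-run `table`.
#' @export
yc_randomize <- function(train, model, method = 1L, n_runs = 100, seed = 1,
                         subtrain_ids = NULL, avg_over = "actives") {
  stopifnot(inherits(train, "mtqsar_dataset"), inherits(model, "mtqsar_lda"))
  if (n_runs < 1) stop("n_runs must be >= 1", call. = FALSE)
  if (is.null(subtrain_ids)) subtrain_ids <- train$ids
  sub_idx <- match(subtrain_ids, train$ids)
  if (anyNA(sub_idx)) stop("subtrain_ids must be training ids", call. = FALSE)

  n <- length(train$ids)
  set.seed(seed)
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    scr <- train
    scr$response <- train$response[sample.int(n)]
    for (cc in names(train$conditions)) {
      scr$conditions[[cc]] <- train$conditions[[cc]][sample.int(n)]
    }
    res <- tryCatch({
      bj <- fit_boxjenkins(scr, method = method, avg_over = avg_over,
                           empty_element = "global-mean")
      feats <- predict(bj, scr)
      missing <- setdiff(model$selected, colnames(feats))
      if (length(missing)) {
        stop("descriptor '", missing[1L],
             "' is not reconstructible from the scrambled data", call. = FALSE)
      }
      X <- feats[sub_idx, model$selected, drop = FALSE]
      y <- scr$response[sub_idx]
      if (length(unique(y)) < 2L || any(apply(X, 2L, stats::sd) == 0)) {
        stop("degenerate randomised fit", call. = FALSE)
      }
      fit <- .lda_fit(X, y)
      lin <- .lda_linear(fit)
      scores <- drop(X %*% lin$coefficients) + lin$intercept
      wl <- wilks_lambda(scores, y)
      acc <- 100 * mean(ifelse(scores > 0, 1L, -1L) == y)
      c(lambda = wl$lambda, accuracy = acc)
    }, error = function(e) {
      if (grepl("not reconstructible", conditionMessage(e))) stop(e)
      c(lambda = NA_real_, accuracy = NA_real_)
    })
    runs[[r]] <- data.frame(run = r, lambda = res[["lambda"]],
                            accuracy = res[["accuracy"]])
  }
  tab <- do.call(rbind, runs)
  structure(list(n_runs = n_runs,
                 lambda_r = mean(tab$lambda, na.rm = TRUE),
                 accuracy_r = mean(tab$accuracy, na.rm = TRUE),
                 table = tab, seed = seed),
            class = "yc_report")
}

#' @export
print.yc_report <- function(x, ...) {
  cat("Y_c-randomisation: ", x$n_runs, " runs\n", sep = "")
  cat(sprintf("  mean randomised Wilks' lambda (lambda_r): %.3f\n", x$lambda_r))
  cat(sprintf("  mean randomised accuracy (accuracy_r):    %.2f%%\n", x$accuracy_r))
  invisible(x)
}

#' @export
as.data.frame.yc_report <- function(x, ...) x$table
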