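# Non-linear modelling: six learners behind a uniform interface, exhaustive
# grid-search hyperparameter tuning by stratified n-fold cross-validation,
# user-specified fits, and applicability-domain flagging by prediction
# confidence.

.LEARNERS <- list(
  knn = list(fit = ".fit_knn", prob = ".prob_knn",
             params = c("n_neighbors", "weights", "algorithm")),
  nb  = list(fit = ".fit_nb", prob = ".prob_nb",
             params = c("alpha", "fit_prior", "binarize")),
  svc = list(fit = ".fit_svc", prob = ".prob_svc",
             params = c("C", "gamma", "kernel", "degree", "coef0")),
  rf  = list(fit = ".fit_rf", prob = ".prob_rf",
             params = c("n_estimators", "criterion", "max_depth",
                        "max_features", "min_samples_leaf",
                        "min_samples_split", "bootstrap")),
  gb  = list(fit = ".fit_gb", prob = ".prob_gb",
             params = c("loss", "learning_rate", "n_estimators", "subsample",
                        "min_samples_split", "min_samples_leaf", "max_depth",
                        "max_features", "criterion")),
  mlp = list(fit = ".fit_mlp", prob = ".prob_mlp",
             params = c("hidden_layer_sizes", "activation", "solver", "alpha",
                        "learning_rate", "learning_rate_init", "max_iter"))
)

.check_learner <- function(learner) {
  learner <- tolower(learner)
  if (!learner %in% names(.LEARNERS)) {
    stop("unknown learner '", learner, "'; available: ",
         paste(names(.LEARNERS), collapse = ", "), call. = FALSE)
  }
  learner
}

.merge_params <- function(defaults, params, learner) {
  bad <- setdiff(names(params), names(defaults))
  if (length(bad)) {
    stop("invalid parameter(s) for learner '", learner, "': ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  }
  defaults[names(params)] <- params
  defaults
}

.fit_learner <- function(learner, X, y, params, seed = NULL) {
  info <- .LEARNERS[[learner]]
  if (!is.null(seed)) set.seed(seed)
  get(info$fit, mode = "function")(X, y, params)
}

.learner_prob <- function(learner, fit, X) {
  get(.LEARNERS[[learner]]$prob, mode = "function")(fit, X)
}

# stratified CV accuracy (percent) of one parameter combination
.cv_accuracy <- function(learner, X, y, params, fold, seed) {
  k <- max(fold)
  acc <- vapply(seq_len(k), function(f) {
    tr <- fold != f
    fit <- .fit_learner(learner, X[tr, , drop = FALSE], y[tr], params,
                        seed = if (!is.null(seed)) seed + f else NULL)
    prob <- .learner_prob(learner, fit, X[!tr, , drop = FALSE])
    mean(ifelse(prob >= 0.5, 1L, -1L) == y[!tr])
  }, numeric(1))
  100 * mean(acc)
}

#' Read a hyperparameter grid from CSV
#'
#' Grid files have one row per parameter: first column the parameter name,
#' second column its candidate values separated by `;`. Values are kept as
#' strings where non-numeric (`True`, `gini`, `None`, ...) and converted to
#' numbers otherwise. The package ships the default grids as
#' `system.file("extdata", "grid_<learner>.csv", package = "mtqsarx")`.
#'
#' @param path CSV file path.
#' @return named list mapping parameter name to value vector/list.
#' @export
read_grid <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, header = TRUE)
  if (ncol(df) < 2L) stop("grid file needs (parameter, values) columns", call. = FALSE)
  grid <- lapply(seq_len(nrow(df)), function(i) {
    vals <- trimws(strsplit(as.character(df[i, 2L]), ";")[[1L]])
    num <- suppressWarnings(as.numeric(vals))
    if (all(!is.na(num))) num else vals
  })
  stats::setNames(grid, trimws(df[[1L]]))
}

#' Exhaustive grid-search hyperparameter tuning
#'
#' Evaluates every combination in the Cartesian product of the grid by
#' stratified n-fold cross-validated accuracy on the sub-training set,
#' refits the best combination on all sub-training rows, and reports the
#' winning parameters with the full evaluation table. Ties break towards
#' the earliest combination in grid order (first parameter varying
#' fastest), so the search is deterministic given the seed.
#'
#' @param features numeric sub-training feature matrix.
#' @param labels sub-training responses in `{+1, -1}`.
#' @param learner one of `"knn"`, `"nb"`, `"svc"`, `"rf"`, `"gb"`, `"mlp"`.
#' @param grid named list mapping parameter names to candidate values (see
#'   [read_grid()]); parameter names are validated against the learner.
#' @param cv_folds number of stratified folds (>= 2; must not exceed the
#'   minority-class count).
#' @param seed integer seed controlling fold assignment and any learner
#'   randomness, or `NULL` for the current RNG state.
#' @return an object of class `mtqsar_classifier` with `learner`, `params`
#'   (the winning combination), `fit`, `cv_accuracy` (percent), and
#'   `cv_table` (one row per combination).
#' @export
grid_search <- function(features, labels, learner, grid, cv_folds = 5,
                        seed = 1) {
  learner <- .check_learner(learner)
  stopifnot(is.matrix(features))
  if (cv_folds < 2) stop("cv_folds must be >= 2", call. = FALSE)
  if (!length(grid)) stop("empty grid", call. = FALSE)
  y <- .validate_response(labels, nrow(features))
  bad <- setdiff(names(grid), .LEARNERS[[learner]]$params)
  if (length(bad)) {
    stop("invalid parameter(s) for learner '", learner, "': ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  }
  fold <- .make_folds(y, cv_folds, if (is.null(seed)) sample.int(1e6, 1) else seed)
  combos <- expand.grid(grid, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)

  best_acc <- -Inf; best_params <- NULL
  accs <- numeric(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    params <- as.list(combos[i, , drop = FALSE])
    names(params) <- names(combos)
    accs[i] <- .cv_accuracy(learner, features, y, params, fold, seed)
    if (accs[i] > best_acc) { best_acc <- accs[i]; best_params <- params }
  }
  fit <- .fit_learner(learner, features, y, best_params, seed = seed)
  cv_table <- cbind(combos, cv_accuracy = accs)
  structure(list(learner = learner, params = best_params, fit = fit,
                 cv_accuracy = best_acc, cv_folds = cv_folds, seed = seed,
                 cv_table = cv_table, mode = "grid"),
            class = "mtqsar_classifier")
}

#' Fit a non-linear classifier with user-specified parameters
#'
#' Single fit, no search: the fast path once suitable hyperparameters are
#' known (e.g. the winners of [grid_search()]). Unspecified parameters fall
#' back to the learner defaults, which are echoed in `$params`.
#'
#' @inheritParams grid_search
#' @param params named list of parameter values (may be empty).
#' @return an `mtqsar_classifier` (see [grid_search()]); `cv_accuracy` is
#'   the stratified n-fold CV accuracy of the given parameters.
#' @export
fit_user <- function(features, labels, learner, params = list(), cv_folds = 5,
                     seed = 1) {
  learner <- .check_learner(learner)
  stopifnot(is.matrix(features))
  y <- .validate_response(labels, nrow(features))
  fold <- .make_folds(y, cv_folds, if (is.null(seed)) sample.int(1e6, 1) else seed)
  cv_acc <- .cv_accuracy(learner, features, y, params, fold, seed)
  fit <- .fit_learner(learner, features, y, params, seed = seed)
  structure(list(learner = learner,
                 params = fit$params %||% params, fit = fit,
                 cv_accuracy = cv_acc, cv_folds = cv_folds, seed = seed,
                 cv_table = NULL, mode = "user"),
            class = "mtqsar_classifier")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mtqsar_classifier <- function(x, ...) {
  cat("Non-linear mt-QSAR classifier: ", x$learner,
      " (", x$mode, " mode)\n", sep = "")
  cat("  parameters: ",
      paste(names(x$params), vapply(x$params, function(v)
        paste(format(unlist(v)), collapse = ","), character(1)),
        sep = "=", collapse = ", "), "\n", sep = "")
  cat(sprintf("  %d-fold CV accuracy: %.2f%%\n", x$cv_folds, x$cv_accuracy))
  invisible(x)
}

#' Predict with confidence and applicability-domain flag
#'
#' The confidence of a prediction is the class-membership score of the
#' predicted class: the posterior probability for probabilistic learners,
#' the fraction of ensemble members voting for it for the forest. A row is
#' inside the applicability domain iff its confidence reaches
#' `confidence_threshold` (default 0.7).
#'
#' @param model an `mtqsar_classifier`.
#' @param features feature matrix to predict.
#' @param confidence_threshold proportion in `[0, 1]`.
#' @return data.frame with `class` (`+1`/`-1`), `prob_positive`,
#'   `confidence` and `in_ad`.
#' @export
predict_with_confidence <- function(model, features, confidence_threshold = 0.7) {
  stopifnot(inherits(model, "mtqsar_classifier"))
  if (confidence_threshold < 0 || confidence_threshold > 1) {
    stop("confidence_threshold must lie in [0, 1]", call. = FALSE)
  }
  prob <- .learner_prob(model$learner, model$fit, features)
  cls <- ifelse(prob >= 0.5, 1L, -1L)
  conf <- ifelse(cls == 1L, prob, 1 - prob)
  data.frame(class = cls, prob_positive = prob, confidence = conf,
             in_ad = conf >= confidence_threshold)
}

#' @export
predict.mtqsar_classifier <- function(object, features, ...) {
  predict_with_confidence(object, features)
}
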