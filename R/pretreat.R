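#' Descriptor pre-treatment: variance and correlation cut-offs
#'
#' Two-stage filter applied to the deviation-descriptor matrix before model
#' building: (a) descriptors whose variance falls below `variance_cutoff`
#' are removed (constant descriptors break every selector downstream);
#' (b) a greedy pairwise correlation filter scans column pairs in stored
#' order and, whenever `|Pearson r| >= correlation_cutoff`, drops the
#' later column of the pair. Both stages are deterministic.
#'
#' @param features numeric matrix (rows = data points).
#' @param variance_cutoff non-negative variance threshold (default 0.001).
#' @param correlation_cutoff threshold in (0, 1] (default 0.999).
#' @return a list with `features` (the surviving columns, original order)
#'   and `report`, a `pretreat_report` holding `removed_constant`,
#'   `removed_correlated` (data.frame kept/dropped/r) and the cut-offs.
#' @export
pretreat <- function(features, variance_cutoff = 0.001,
                     correlation_cutoff = 0.999) {
  stopifnot(is.matrix(features), nrow(features) >= 2)
  if (variance_cutoff < 0) stop("variance_cutoff must be >= 0", call. = FALSE)
  if (correlation_cutoff <= 0 || correlation_cutoff > 1) {
    stop("correlation_cutoff must lie in (0, 1]", call. = FALSE)
  }
  vars <- apply(features, 2L, stats::var)
  removed_constant <- colnames(features)[vars < variance_cutoff]
  keep <- colnames(features)[vars >= variance_cutoff]
  if (!length(keep)) stop("variance filter removed every descriptor", call. = FALSE)

  X <- features[, keep, drop = FALSE]
  kept <- rep(TRUE, ncol(X))
  pairs <- list()
  if (ncol(X) >= 2L) {
    cm <- suppressWarnings(stats::cor(X))
    cm[is.na(cm)] <- 0
    for (i in seq_len(ncol(X) - 1L)) {
      if (!kept[i]) next
      for (j in seq.int(i + 1L, ncol(X))) {
        if (!kept[j]) next
        if (abs(cm[i, j]) >= correlation_cutoff - 1e-10) {
          kept[j] <- FALSE
          pairs[[length(pairs) + 1L]] <-
            data.frame(kept = colnames(X)[i], dropped = colnames(X)[j],
                       r = cm[i, j], stringsAsFactors = FALSE)
        }
      }
    }
  }
  removed_correlated <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(kept = character(0), dropped = character(0), r = numeric(0))
  X <- X[, kept, drop = FALSE]
  if (!ncol(X)) stop("correlation filter removed every descriptor", call. = FALSE)
  report <- structure(
    list(removed_constant = removed_constant,
         removed_correlated = removed_correlated,
         variance_cutoff = variance_cutoff,
         correlation_cutoff = correlation_cutoff),
    class = "pretreat_report")
  list(features = X, report = report)
}

#' @export
print.pretreat_report <- function(x, ...) {
  cat("Pre-treatment (variance cut-off ", x$variance_cutoff,
      ", correlation cut-off ", x$correlation_cutoff, ")\n", sep = "")
  cat("  low-variance removed: ", length(x$removed_constant), "\n", sep = "")
  cat("  correlation removed:  ", nrow(x$removed_correlated), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.pretreat_report <- function(x, ...) {
  rbind(
    if (length(x$removed_constant))
      data.frame(rule = "variance", kept = NA_character_,
                 dropped = x$removed_constant, r = NA_real_),
    if (nrow(x$removed_correlated))
      cbind(rule = "correlation", x$removed_correlated),
    data.frame(rule = "cutoffs", kept = as.character(x$correlation_cutoff),
               dropped = as.character(x$variance_cutoff), r = NA_real_)
  )
}

#' Cross-correlation matrix of selected descriptors
#'
#' Pairwise Pearson correlations among the columns of a (selected)
#' descriptor matrix, used to diagnose inter-collinearity of a fitted
#' linear model. Constant columns have undefined correlations, reported as
#' `NA` with a warning.
#'
#' @param features numeric matrix with >= 2 columns.
#' @return a symmetric correlation matrix with unit diagonal and attribute
#'   `max_abs_offdiag`, the largest absolute off-diagonal entry (`NA`s
#'   ignored).
#' @export
cross_correlation <- function(features) {
  stopifnot(is.matrix(features))
  if (ncol(features) < 2L) stop("need at least two selected descriptors", call. = FALSE)
  sds <- apply(features, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("constant descriptor(s) have undefined correlations: ",
            paste(colnames(features)[sds == 0], collapse = ", "))
  }
  cm <- suppressWarnings(stats::cor(features))
  diag(cm) <- 1
  off <- abs(cm[upper.tri(cm)])
  attr(cm, "max_abs_offdiag") <- if (all(is.na(off))) NA_real_ else max(off, na.rm = TRUE)
  cm
}
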