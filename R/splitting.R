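# Dataset division: training/validation first (three schemes), then the
# training rows are sub-divided into sub-training and test (calibration)
# after the deviation descriptors are computed. The validation set is the
# "ideal test set": it never participates in descriptor statistics.

round_half_up <- function(x) floor(x + 0.5)

.new_split <- function(ids, set, scheme, params) {
  stopifnot(length(ids) == length(set))
  structure(
    data.frame(id = ids, set = set, stringsAsFactors = FALSE),
    scheme = scheme, params = params, class = c("mtqsar_split", "data.frame")
  )
}

#' @export
print.mtqsar_split <- function(x, ...) {
  cat("mt-QSAR split [", attr(x, "scheme"), "]: ",
      paste(sprintf("%s=%d", names(table(x$set)), as.integer(table(x$set))),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

.check_partition <- function(split, ds) {
  if (!setequal(split$id, ds$ids) || nrow(split) != length(ds$ids)) {
    stop("internal error: split is not an exact partition of the dataset", call. = FALSE)
  }
  invisible(split)
}

#' Training/validation division from pre-defined tags
#'
#' Rows tagged `"Train"` go to the training set and rows tagged `"Test"` to
#' the validation set, exactly as tagged. Used to reproduce a data
#' distribution fixed by an earlier study or another tool.
#'
#' @param ds an [mtqsar_dataset()] with a complete `set_tag` column.
#' @return an object of class `mtqsar_split`: a data.frame with columns
#'   `id` and `set` (`"training"`/`"validation"`), with the scheme and its
#'   parameters stored as attributes.
#' @export
split_predefined <- function(ds) {
  stopifnot(inherits(ds, "mtqsar_dataset"))
  if (is.null(ds$set_tag)) stop("dataset carries no set_tag column", call. = FALSE)
  set <- ifelse(ds$set_tag == "Train", "training", "validation")
  if (!any(set == "validation")) warning("pre-defined division yields an empty validation set")
  if (!any(set == "training")) warning("pre-defined division yields an empty training set")
  .check_partition(.new_split(ds$ids, set, "predefined", list()), ds)
}

#' Random training/validation division
#'
#' Draws `round(validation_fraction * n)` rows (round half up) uniformly at
#' random into the validation set. The same seed always reproduces the same
#' partition; changing the seed gives a different one.
#'
#' @param ds an [mtqsar_dataset()].
#' @param validation_fraction proportion in (0, 1) of rows for validation.
#' @param seed integer random seed.
#' @return an `mtqsar_split` (see [split_predefined()]).
#' @export
split_random <- function(ds, validation_fraction, seed) {
  stopifnot(inherits(ds, "mtqsar_dataset"))
  if (validation_fraction <= 0 || validation_fraction >= 1) {
    stop("validation_fraction must lie strictly inside (0,1)", call. = FALSE)
  }
  n <- length(ds$ids)
  m <- round_half_up(validation_fraction * n)
  if (m < 1L || m >= n) {
    stop("validation_fraction ", validation_fraction, " leaves ", m,
         " of ", n, " rows for validation", call. = FALSE)
  }
  set.seed(seed)
  vd <- sample.int(n, m)
  set <- rep("training", n)
  set[vd] <- "validation"
  .check_partition(
    .new_split(ds$ids, set, "random",
               list(validation_fraction = validation_fraction, seed = seed)),
    ds)
}

#' k-means cluster analysis (kMCA) based division
#'
#' The dataset is clustered into `n_clusters` groups by k-means on z-scored
#' input descriptors; within each cluster, `round(fraction * cluster size)`
#' rows (round half up) are drawn uniformly into the validation set, so the
#' validation set covers all regions of descriptor space. Sampling within
#' clusters is unstratified with respect to the response (recorded in the
#' provenance). Descriptors with zero variance are excluded from the
#' clustering; if all of them are constant the scheme degenerates to a
#' single cluster (i.e. a plain random division).
#'
#' @param ds an [mtqsar_dataset()].
#' @param n_clusters number of k-means clusters, in `[1, n]`.
#' @param validation_fraction proportion in (0, 1) drawn from each cluster.
#' @param seed integer seed for both centroid initialisation (10 restarts)
#'   and within-cluster sampling.
#' @return an `mtqsar_split`; the provenance records the cluster sizes.
#' @export
split_kmca <- function(ds, n_clusters, validation_fraction, seed) {
  stopifnot(inherits(ds, "mtqsar_dataset"))
  n <- length(ds$ids)
  if (n_clusters < 1 || n_clusters > n) {
    stop("n_clusters must lie in [1, ", n, "]", call. = FALSE)
  }
  if (validation_fraction <= 0 || validation_fraction >= 1) {
    stop("validation_fraction must lie strictly inside (0,1)", call. = FALSE)
  }
  X <- ds$descriptors
  sds <- apply(X, 2L, stats::sd)
  keep <- which(sds > 0)
  set.seed(seed)
  if (length(keep) == 0L || n_clusters == 1L) {
    cluster <- rep(1L, n)
  } else {
    Z <- scale(X[, keep, drop = FALSE])
    km <- stats::kmeans(Z, centers = min(n_clusters, nrow(unique(Z))),
                        nstart = 10, iter.max = 50)
    cluster <- km$cluster
  }
  set <- rep("training", n)
  for (k in sort(unique(cluster))) {
    rows <- which(cluster == k)
    m <- round_half_up(validation_fraction * length(rows))
    if (m >= 1L) set[rows[sample.int(length(rows), m)]] <- "validation"
  }
  if (!any(set == "validation")) {
    stop("kMCA division produced an empty validation set", call. = FALSE)
  }
  sizes <- as.integer(table(cluster))
  .check_partition(
    .new_split(ds$ids, set, "kmca",
               list(n_clusters = n_clusters,
                    validation_fraction = validation_fraction, seed = seed,
                    cluster_sizes = sizes)),
    ds)
}

#' Sub-divide the training set into sub-training and test sets
#'
#' Applied after the first-stage division (and, in the modelling pipeline,
#' after the Box-Jenkins transform): `round(test_fraction * n_training)`
#' training rows (round half up) become the test (calibration) set, the rest
#' the sub-training set. Validation labels are passed through untouched.
#'
#' @param split an `mtqsar_split` from one of the first-stage schemes.
#' @param test_fraction proportion in (0, 1) of training rows for the test set.
#' @param seed integer seed.
#' @return an `mtqsar_split` with set labels in
#'   `{"sub-training", "test", "validation"}`.
#' @export
split_subtrain_test <- function(split, test_fraction, seed) {
  stopifnot(inherits(split, "mtqsar_split"))
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must lie strictly inside (0,1)", call. = FALSE)
  }
  tr <- which(split$set == "training")
  if (!length(tr)) stop("split contains no training rows", call. = FALSE)
  m <- round_half_up(test_fraction * length(tr))
  if (m < 1L || m >= length(tr)) {
    stop("test_fraction ", test_fraction, " leaves ", m, " of ", length(tr),
         " training rows for the test set", call. = FALSE)
  }
  set.seed(seed)
  ts <- tr[sample.int(length(tr), m)]
  set <- split$set
  set[tr] <- "sub-training"
  set[ts] <- "test"
  params <- attr(split, "params")
  params$test_fraction <- test_fraction
  params$subtrain_seed <- seed
  .new_split(split$id, set, paste0(attr(split, "scheme"), "+subtrain"), params)
}

#' Extract the rows of a dataset belonging to one split set
#'
#' @param ds an [mtqsar_dataset()].
#' @param split an `mtqsar_split` over the same ids.
#' @param set one of the set labels present in `split`.
#' @return an [mtqsar_dataset()] with the matching rows.
#' @export
split_subset <- function(ds, split, set) {
  stopifnot(inherits(ds, "mtqsar_dataset"), inherits(split, "mtqsar_split"))
  ids <- split$id[split$set == set]
  if (!length(ids)) stop("split has no rows with set label '", set, "'", call. = FALSE)
  subset_rows(ds, ids)
}
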