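# The Box-Jenkins moving-average operators turn externally computed input
# descriptors D_i into condition-dependent deviation descriptors, one block
# per condition column:
#
#   Method 1:  d = D_i - avg(D_i | element)
#   Method 2:  d = (D_i - avg) / (D_max - D_min)
#   Method 3:  d = (D_i - avg) / ((D_max - D_min) * p_c(element))
#   Method 4:  d = (D_i - avg) / p_user(row)
#
# avg(D_i | element) is the arithmetic mean of D_i over the ACTIVE (+1)
# training rows sharing that condition element; D_max/D_min are taken over
# all training rows (ranges are class-free); p_c(element) is the number of
# training actives in the element divided by the total training size. All
# statistics are frozen at fit time: transforming validation rows reuses the
# training statistics and never recomputes anything (leakage safety).

#' Fit a Box-Jenkins moving-average model on training data
#'
#' @param train an [mtqsar_dataset()] holding the training rows only.
#' @param method operator id, integer 1-4 (see Details).
#' @param avg_over `"actives"` (default): element means are computed over
#'   `+1` training rows only, as in the moving-average mt-QSAR literature;
#'   `"all"` averages over every training row (alternative reading, exposed
#'   so the two conventions can be compared).
#' @details Methods 2 and 3 cannot work with invariant descriptors (zero
#'   training range); those are removed at fit time and recorded in
#'   `$dropped`. Method 3 additionally stores the a-priori probability
#'   factor of each element, `p_c = n_active(element) / n_train`. Method 4
#'   divides by a strictly positive per-row user factor `p_user`, which must
#'   be present on the training rows at fit time and on any rows passed to
#'   [predict.boxjenkins()].
#' @param empty_element what to do when an element present in training has
#'   no rows to average over (only possible with `avg_over = "actives"`
#'   when an element has zero actives): `"error"` (default) aborts naming
#'   the offending (column, element); `"global-mean"` substitutes the
#'   overall mean of the averaging rows — used internally by
#'   [yc_randomize()], where scrambled responses can empty an element.
#' @return an object of class `boxjenkins` with elements `method`, `avg`
#'   (per condition column: element x descriptor mean matrix), `range`
#'   (2 x descriptor matrix, rows `min`/`max`), `p_c`, `global_avg` (overall
#'   active mean per descriptor, used by the unseen-element fallback),
#'   `descriptors` (retained descriptor names), `dropped`, `n_train`.
#' @export
fit_boxjenkins <- function(train, method = 1L, avg_over = c("actives", "all"),
                           empty_element = c("error", "global-mean")) {
  stopifnot(inherits(train, "mtqsar_dataset"))
  method <- as.integer(method)
  if (!method %in% 1:4) stop("method must be one of 1, 2, 3, 4", call. = FALSE)
  avg_over <- match.arg(avg_over)
  empty_element <- match.arg(empty_element)
  if (method == 4L && is.null(train$p_user)) {
    stop("Method 4 requires a p_user column on the training data ",
         "(supply it in the dataset or via compute_probability_factors())",
         call. = FALSE)
  }

  X <- train$descriptors
  n <- nrow(X)
  rng <- rbind(min = apply(X, 2L, min), max = apply(X, 2L, max))
  dropped <- character(0)
  if (method %in% c(2L, 3L)) {
    invariant <- colnames(X)[rng["max", ] <= rng["min", ]]
    if (length(invariant) == ncol(X)) {
      stop("all descriptors are invariant; Methods 2/3 cannot be fitted", call. = FALSE)
    }
    dropped <- invariant
    X <- X[, setdiff(colnames(X), invariant), drop = FALSE]
    rng <- rng[, colnames(X), drop = FALSE]
  }

  base_rows <- if (avg_over == "actives") which(train$response == 1L) else seq_len(n)
  if (!length(base_rows)) stop("training set contains no active (+1) rows", call. = FALSE)

  avg <- list(); p_c <- list()
  for (cc in names(train$conditions)) {
    elems <- sort(unique(train$conditions[[cc]]))
    m <- matrix(NA_real_, nrow = length(elems), ncol = ncol(X),
                dimnames = list(elems, colnames(X)))
    pc <- stats::setNames(numeric(length(elems)), elems)
    for (e in elems) {
      rows <- base_rows[train$conditions[[cc]][base_rows] == e]
      if (!length(rows)) {
        if (empty_element == "error") {
          stop("condition column '", cc, "', element '", e, "' has no ",
               if (avg_over == "actives") "active " else "", "training rows; ",
               "cannot compute its descriptor average", call. = FALSE)
        }
        m[e, ] <- colMeans(X[base_rows, , drop = FALSE])
      } else {
        m[e, ] <- colMeans(X[rows, , drop = FALSE])
      }
      pc[e] <- sum(train$response == 1L & train$conditions[[cc]] == e) / n
    }
    if (method == 3L && any(pc == 0)) {
      # a zero active count would divide by zero in the Method 3 operator;
      # floor it at half a count (pseudo-count), reachable only with
      # avg_over = "all" or the global-mean fallback
      pc[pc == 0] <- 0.5 / n
    }
    avg[[cc]] <- m
    p_c[[cc]] <- pc
  }

  structure(list(method = method, avg_over = avg_over, avg = avg,
                 range = rng, p_c = p_c,
                 global_avg = colMeans(X[base_rows, , drop = FALSE]),
                 descriptors = colnames(X), dropped = dropped, n_train = n),
            class = "boxjenkins")
}

#' @export
print.boxjenkins <- function(x, ...) {
  cat("Box-Jenkins moving-average model (Method", x$method, ")\n", sep = "")
  cat("  fitted on ", x$n_train, " training rows; element means over ",
      x$avg_over, "\n", sep = "")
  cat("  ", length(x$descriptors), " retained descriptor(s), ",
      length(x$dropped), " invariant dropped\n", sep = "")
  for (cc in names(x$avg)) {
    cat("  condition '", cc, "': ", nrow(x$avg[[cc]]), " element(s)\n", sep = "")
  }
  invisible(x)
}

#' Compute deviation descriptors from a fitted Box-Jenkins model
#'
#' Applies the frozen training statistics to any rows (sub-training, test or
#' validation): one deviation block per condition column, named
#' `d(<descriptor>)_<column>`. Nothing is recomputed from `newdata`.
#'
#' @param object a fitted [fit_boxjenkins()] model.
#' @param newdata an [mtqsar_dataset()] carrying every condition column the
#'   model knows (and `p_user` for Method 4).
#' @param unseen what to do with a condition element never seen at fit time:
#'   `"error"` (default) aborts naming the element; `"global-active-mean"`
#'   substitutes the overall training active mean of each descriptor.
#' @param ... unused.
#' @return numeric matrix, `nrow(newdata)` x
#'   `length(object$descriptors) * n_condition_columns`, with row names set
#'   to the dataset ids.
#' @export
predict.boxjenkins <- function(object, newdata,
                               unseen = c("error", "global-active-mean"), ...) {
  stopifnot(inherits(newdata, "mtqsar_dataset"))
  unseen <- match.arg(unseen)
  missing_cols <- setdiff(names(object$avg), names(newdata$conditions))
  if (length(missing_cols)) {
    stop("rows are missing condition column(s): ",
         paste(sQuote(missing_cols), collapse = ", "), call. = FALSE)
  }
  if (object$method == 4L && is.null(newdata$p_user)) {
    stop("Method 4 requires p_user on the rows being transformed", call. = FALSE)
  }
  X <- newdata$descriptors[, object$descriptors, drop = FALSE]
  n <- nrow(X)
  span <- object$range["max", ] - object$range["min", ]

  blocks <- lapply(names(object$avg), function(cc) {
    elems <- newdata$conditions[[cc]]
    known <- rownames(object$avg[[cc]])
    unseen_elems <- setdiff(unique(elems), known)
    A <- matrix(NA_real_, n, length(object$descriptors))
    hit <- elems %in% known
    if (any(hit)) A[hit, ] <- object$avg[[cc]][elems[hit], , drop = FALSE]
    if (length(unseen_elems)) {
      if (unseen == "error") {
        stop("condition column '", cc, "', element '", unseen_elems[1L],
             "' was never seen in training (set unseen = ",
             "'global-active-mean' to fall back to the overall active mean)",
             call. = FALSE)
      }
      A[!hit, ] <- matrix(object$global_avg, sum(!hit),
                          length(object$descriptors), byrow = TRUE)
    }
    d <- X - A
    if (object$method == 2L) {
      d <- sweep(d, 2L, span, "/")
    } else if (object$method == 3L) {
      p <- rep(NA_real_, n)
      p[hit] <- object$p_c[[cc]][elems[hit]]
      if (any(!hit)) p[!hit] <- sum(unlist(object$p_c[[cc]])) /
        length(object$p_c[[cc]]) # grand-mean fallback, only reachable when unseen allowed
      d <- sweep(d, 2L, span, "/") / p
    } else if (object$method == 4L) {
      d <- d / newdata$p_user
    }
    colnames(d) <- paste0("d(", object$descriptors, ")_", cc)
    d
  })
  out <- do.call(cbind, blocks)
  rownames(out) <- newdata$ids
  out
}

#' Composite probability factors from primary/secondary condition links
#'
#' Builds per-row a-priori probability factors for the Method 4 operator
#' from element frequencies in the training set. A *linked* primary column
#' contributes, per row, the ratio `n_T(primary element) / N_T(secondary
#' element)` where both counts run over all training rows (actives and
#' inactives alike); an *unlinked* column contributes `n_T(element) / N_T`
#' with `N_T` the training size. The returned factor is the product over the
#' requested condition columns.
#'
#' @param train an [mtqsar_dataset()] of training rows (the counting basis).
#' @param links named character vector mapping primary condition column ->
#'   secondary condition column, e.g.
#'   `c(measure = "lethality", species = "target_map")`. Columns of `train`
#'   not named here and not used as a secondary column are treated as
#'   unlinked contributors. Use `links = character(0)` for frequency-only
#'   factors.
#' @param newdata optional [mtqsar_dataset()] for which the factors are
#'   evaluated (counts still come from `train`); defaults to `train`. An
#'   element of `newdata` absent from `train` makes its count zero and is an
#'   error.
#' @return numeric vector of strictly positive composite factors, one per
#'   row of `newdata`.
#' @export
compute_probability_factors <- function(train, links = character(0),
                                        newdata = train) {
  stopifnot(inherits(train, "mtqsar_dataset"), inherits(newdata, "mtqsar_dataset"))
  cols <- names(train$conditions)
  if (length(links)) {
    if (is.null(names(links)) || any(!nzchar(names(links)))) {
      stop("links must be a named vector: primary -> secondary", call. = FALSE)
    }
    bad <- setdiff(c(names(links), unname(links)), cols)
    if (length(bad)) {
      stop("linked column(s) absent from the dataset: ",
           paste(sQuote(bad), collapse = ", "), call. = FALSE)
    }
  }
  n_T <- length(train$ids)
  count_of <- function(column, elems) {
    tab <- table(train$conditions[[column]])
    cnt <- as.numeric(tab[elems])
    if (anyNA(cnt) || any(cnt == 0)) {
      miss <- elems[is.na(cnt) | cnt == 0][1L]
      stop("element '", miss, "' of column '", column,
           "' has zero training count; its probability factor is undefined",
           call. = FALSE)
    }
    cnt
  }
  contributing <- setdiff(cols, unname(links))
  p <- rep(1, length(newdata$ids))
  for (cc in contributing) {
    num <- count_of(cc, newdata$conditions[[cc]])
    if (cc %in% names(links)) {
      sec <- links[[cc]]
      den <- count_of(sec, newdata$conditions[[sec]])
    } else {
      den <- n_T
    }
    p <- p * num / den
  }
  p
}
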