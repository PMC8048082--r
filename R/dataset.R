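#' Construct an mt-QSAR dataset
#'
#' The central container for multitarget QSAR modelling: one row per data
#' point, i.e. per (compound, experimental condition) combination. Each row
#' carries a unique case identifier, a binary response coded `+1` (active /
#' positive) or `-1` (inactive / negative), one element for every categorical
#' condition column of the ontology (e.g. biological target, cell line,
#' mutation status), a numeric input-descriptor vector, and optionally a
#' pre-defined set tag (`"Train"`/`"Test"`) and a user-supplied probability
#' factor `p_user` used by the Method 4 moving-average operator.
#'
#' Input descriptors are assumed to be computed externally (e.g. by DRAGON or
#' QuBiLS-MAS); descriptor calculation is out of scope for this package.
#'
#' @param ids character or integer vector of unique case identifiers.
#' @param response vector coercible to integer with values in `{+1, -1}`.
#'   `{0, 1}` coding is rejected, not remapped.
#' @param conditions data.frame of categorical condition columns; every cell
#'   must be a non-empty string.
#' @param descriptors numeric matrix or data.frame of input descriptors;
#'   column order is preserved and meaningful (deterministic tie-breaking
#'   downstream).
#' @param set_tag optional character vector with values `"Train"`/`"Test"`.
#' @param p_user optional numeric vector, strictly positive.
#' @return An object of class `mtqsar_dataset`: a list with elements `ids`,
#'   `response`, `conditions` (data.frame of character columns),
#'   `descriptors` (numeric matrix with column names), `set_tag`, `p_user`.
#' @examples
#' ds <- mtqsar_dataset(
#'   ids = paste0("c", 1:4),
#'   response = c(1, 1, -1, -1),
#'   conditions = data.frame(target = c("A", "A", "B", "B")),
#'   descriptors = cbind(X1 = c(1, 3, 2, 4), X2 = c(0, 1, 0, 1))
#' )
#' nrow_mtqsar(ds)
#' @export
mtqsar_dataset <- function(ids, response, conditions, descriptors,
                           set_tag = NULL, p_user = NULL) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1L]
    stop("duplicate id: '", dup, "'", call. = FALSE)
  }
  n <- length(ids)

  response <- .validate_response(response, n)

  if (!is.data.frame(conditions)) conditions <- as.data.frame(conditions)
  if (nrow(conditions) != n) stop("conditions must have one row per id", call. = FALSE)
  if (ncol(conditions) < 1L) stop("at least one condition column is required", call. = FALSE)
  conditions[] <- lapply(conditions, as.character)
  for (cc in names(conditions)) {
    bad <- which(is.na(conditions[[cc]]) | !nzchar(conditions[[cc]]))
    if (length(bad)) {
      stop("empty condition element in column '", cc, "' at row ", bad[1L],
           call. = FALSE)
    }
  }

  descriptors <- .validate_descriptors(descriptors, n)

  if (!is.null(set_tag)) {
    set_tag <- as.character(set_tag)
    if (length(set_tag) != n) stop("set_tag length mismatch", call. = FALSE)
    bad <- which(!set_tag %in% c("Train", "Test"))
    if (length(bad)) {
      stop("set_tag value outside {'Train','Test'} at row ", bad[1L],
           " ('", set_tag[bad[1L]], "')", call. = FALSE)
    }
  }
  if (!is.null(p_user)) {
    p_user <- as.numeric(p_user)
    if (length(p_user) != n) stop("p_user length mismatch", call. = FALSE)
    bad <- which(!is.finite(p_user) | p_user <= 0)
    if (length(bad)) {
      stop("p_user must be strictly positive and finite (row ", bad[1L], ")",
           call. = FALSE)
    }
  }

  structure(
    list(ids = ids, response = response, conditions = conditions,
         descriptors = descriptors, set_tag = set_tag, p_user = p_user),
    class = "mtqsar_dataset"
  )
}

.validate_response <- function(response, n, rows = NULL, column = "response") {
  rnum <- suppressWarnings(as.numeric(as.character(response)))
  if (length(rnum) != n) stop("response length mismatch", call. = FALSE)
  bad <- which(is.na(rnum) | !rnum %in% c(-1, 1))
  if (length(bad)) {
    row_lab <- if (is.null(rows)) bad[1L] else rows[bad[1L]]
    stop("response value outside {+1,-1} in column '", column, "' at row ",
         row_lab, " ('", as.character(response)[bad[1L]], "')", call. = FALSE)
  }
  as.integer(rnum)
}

.validate_descriptors <- function(descriptors, n, rows = NULL) {
  if (is.data.frame(descriptors)) {
    for (dc in names(descriptors)) {
      v <- descriptors[[dc]]
      if (!is.numeric(v)) {
        vnum <- suppressWarnings(as.numeric(as.character(v)))
        bad <- which(is.na(vnum) & !is.na(as.character(v)))
        if (length(bad)) {
          row_lab <- if (is.null(rows)) bad[1L] else rows[bad[1L]]
          stop("non-numeric descriptor cell in column '", dc, "' at row ",
               row_lab, " ('", as.character(v)[bad[1L]], "')", call. = FALSE)
        }
        descriptors[[dc]] <- vnum
      }
    }
    descriptors <- as.matrix(descriptors)
  }
  storage.mode(descriptors) <- "double"
  if (nrow(descriptors) != n) stop("descriptor row count mismatch", call. = FALSE)
  if (is.null(colnames(descriptors))) {
    colnames(descriptors) <- paste0("X", seq_len(ncol(descriptors)))
  }
  if (any(!is.finite(descriptors))) {
    idx <- which(!is.finite(descriptors), arr.ind = TRUE)[1L, ]
    row_lab <- if (is.null(rows)) idx[1L] else rows[idx[1L]]
    stop("missing or non-finite descriptor value in column '",
         colnames(descriptors)[idx[2L]], "' at row ", row_lab,
         " (no imputation is performed)", call. = FALSE)
  }
  descriptors
}

#' @export
print.mtqsar_dataset <- function(x, ...) {
  cat("mt-QSAR dataset: ", length(x$ids), " data points, ",
      ncol(x$descriptors), " input descriptors, ",
      ncol(x$conditions), " condition column(s) [",
      paste(names(x$conditions), collapse = ", "), "]\n", sep = "")
  cat("  actives (+1): ", sum(x$response == 1L), ", inactives (-1): ",
      sum(x$response == -1L), "\n", sep = "")
  if (!is.null(x$set_tag)) {
    cat("  pre-defined tags: ", sum(x$set_tag == "Train"), " Train / ",
        sum(x$set_tag == "Test"), " Test\n", sep = "")
  }
  if (!is.null(x$p_user)) cat("  p_user column present\n")
  invisible(x)
}

#' Number of data points in a dataset
#' @param ds an [mtqsar_dataset()].
#' @return integer row count.
#' @export
nrow_mtqsar <- function(ds) length(ds$ids)

#' Subset a dataset by row index or id
#'
#' @param ds an [mtqsar_dataset()].
#' @param i integer/logical row index, or character vector of ids.
#' @return a new `mtqsar_dataset` with the selected rows, in the given order.
#' @export
subset_rows <- function(ds, i) {
  if (is.character(i)) {
    pos <- match(i, ds$ids)
    if (anyNA(pos)) stop("unknown id: '", i[which(is.na(pos))[1L]], "'", call. = FALSE)
    i <- pos
  }
  mtqsar_dataset(
    ids = ds$ids[i],
    response = ds$response[i],
    conditions = ds$conditions[i, , drop = FALSE],
    descriptors = ds$descriptors[i, , drop = FALSE],
    set_tag = if (!is.null(ds$set_tag)) ds$set_tag[i],
    p_user = if (!is.null(ds$p_user)) ds$p_user[i]
  )
}

#' Declare the column roles of a delimited mt-QSAR table
#'
#' Column roles are declared explicitly (never inferred from position)
#' because real condition ontologies vary in width: two to seven categorical
#' condition columns are all in routine use.
#'
#' @param id name of the case-identifier column.
#' @param response name of the `+1`/`-1` response column.
#' @param conditions character vector of condition column names (>= 1).
#' @param descriptors character vector of descriptor column names, or `NULL`
#'   to take every column not claimed by another role, in file order.
#' @param set_tag optional name of the `"Train"`/`"Test"` tag column.
#' @param p_user optional name of the user probability-factor column.
#' @return a list of class `mtqsar_schema`.
#' @seealso [read_schema()] to load the same declaration from a YAML file.
#' @export
mtqsar_schema <- function(id, response, conditions, descriptors = NULL,
                          set_tag = NULL, p_user = NULL) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(response), length(response) == 1L,
            is.character(conditions), length(conditions) >= 1L)
  structure(list(id = id, response = response, conditions = conditions,
                 descriptors = descriptors, set_tag = set_tag,
                 p_user = p_user),
            class = "mtqsar_schema")
}

#' Read a column-role declaration from a YAML file
#'
#' @param path YAML file with keys `id`, `response`, `conditions` and
#'   optionally `descriptors`, `set_tag`, `p_user`.
#' @return an [mtqsar_schema()].
#' @export
read_schema <- function(path) {
  y <- yaml::read_yaml(path)
  for (k in c("id", "response", "conditions")) {
    if (is.null(y[[k]])) stop("schema file misses required key '", k, "'", call. = FALSE)
  }
  mtqsar_schema(id = y$id, response = y$response,
                conditions = as.character(y$conditions),
                descriptors = if (!is.null(y$descriptors)) as.character(y$descriptors),
                set_tag = y$set_tag, p_user = y$p_user)
}

#' Read and validate an mt-QSAR dataset from CSV
#'
#' Reads an RFC-4180 style CSV (`.` decimal separator) and validates it
#' against the declared column roles. Descriptor column order is preserved.
#'
#' @param path CSV file path.
#' @param schema an [mtqsar_schema()] or the path of a YAML schema file.
#' @return an [mtqsar_dataset()].
#' @export
read_mtqsar <- function(path, schema) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.character(schema)) schema <- read_schema(schema)
  stopifnot(inherits(schema, "mtqsar_schema"))
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)

  declared <- c(schema$id, schema$response, schema$conditions,
                schema$descriptors, schema$set_tag, schema$p_user)
  missing <- setdiff(declared, names(df))
  if (length(missing)) {
    stop("declared column(s) absent from file: ",
         paste(sQuote(missing), collapse = ", "), call. = FALSE)
  }
  desc_cols <- schema$descriptors
  if (is.null(desc_cols)) {
    claimed <- c(schema$id, schema$response, schema$conditions,
                 schema$set_tag, schema$p_user)
    desc_cols <- setdiff(names(df), claimed)
    if (!length(desc_cols)) stop("no descriptor columns left after role assignment", call. = FALSE)
  }

  mtqsar_dataset(
    ids = df[[schema$id]],
    response = df[[schema$response]],
    conditions = df[schema$conditions],
    descriptors = df[desc_cols],
    set_tag = if (!is.null(schema$set_tag)) df[[schema$set_tag]],
    p_user = if (!is.null(schema$p_user)) df[[schema$p_user]]
  )
}

#' Write an mt-QSAR dataset to CSV
#'
#' The inverse of [read_mtqsar()]: writes one column per role in the order
#' id, response, conditions, descriptors, then optional `set_tag`, `p_user`.
#' Reading the file back with the matching schema reproduces the dataset
#' exactly (values and column order).
#'
#' @param ds an [mtqsar_dataset()].
#' @param path output CSV path.
#' @return (invisibly) the [mtqsar_schema()] describing the written file.
#' @export
write_mtqsar <- function(ds, path) {
  stopifnot(inherits(ds, "mtqsar_dataset"))
  df <- data.frame(id = ds$ids, response = ds$response,
                   check.names = FALSE, stringsAsFactors = FALSE)
  df <- cbind(df, ds$conditions, as.data.frame(ds$descriptors))
  if (!is.null(ds$set_tag)) df$set_tag <- ds$set_tag
  if (!is.null(ds$p_user)) df$p_user <- ds$p_user
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(mtqsar_schema(
    id = "id", response = "response", conditions = names(ds$conditions),
    descriptors = colnames(ds$descriptors),
    set_tag = if (!is.null(ds$set_tag)) "set_tag",
    p_user = if (!is.null(ds$p_user)) "p_user"
  ))
}

#' Write a tabular report to CSV
#'
#' All report objects in the package (classification reports, condition-wise
#' tables, pre-treatment logs, ...) are plain data.frames or coercible to
#' one; this writes them as delimited text, re-readable losslessly. Cells
#' that are undefined (e.g. a condition tuple absent from a set) are written
#' as the literal string `"na"`.
#'
#' @param report a data.frame (or object with an `as.data.frame` method).
#' @param path output CSV path.
#' @return invisibly, the data.frame that was written.
#' @export
write_report <- function(report, path) {
  df <- as.data.frame(report)
  if (!nrow(df)) stop("refusing to write an empty report", call. = FALSE)
  out <- df
  out[] <- lapply(out, function(v) {
    v <- as.character(v)
    v[is.na(v)] <- "na"
    v
  })
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}
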