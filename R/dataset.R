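#' Rectangular dataset with missingness mask and column typing
#'
#' The basic container used throughout the package: a numeric value matrix
#' (subjects in rows, variables in columns), a logical observation mask of
#' the same shape (`TRUE` = observed), and a per-column type tag,
#' `"binary"` or `"continuous"`.  Binary columns are coded 0/1 but stored
#' as reals so that every conditional model works in plain matrix algebra.
#'
#' Cells flagged unobserved carry `NA` in `values`.  When a mask is
#' applied to simulated data the pre-masking values are retained in the
#' `truth` field for validation only; no imputation routine in this
#' package reads `truth` (the imputers receive `values`, in which masked
#' cells are `NA`, so the barrier is structural).
#'
#' @param values numeric matrix with column names; `NA` marks unobserved
#'   cells.
#' @param mask logical matrix, same shape as `values`; defaults to
#'   `!is.na(values)`.
#' @param types character vector of `"binary"`/`"continuous"`, one per
#'   column.  Guessed from the observed values (all in \{0, 1\} => binary)
#'   when omitted.
#' @param truth optional numeric matrix holding the complete data before
#'   masking; used only by validation code and tests.
#' @return an object of class `md_dataset`.
#' @export
md_dataset <- function(values, mask = !is.na(values), types = NULL,
                       truth = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L || ncol(values) < 2L)
    stop("need at least 1 row and 2 columns")
  if (is.null(colnames(values)))
    colnames(values) <- paste0("X", seq_len(ncol(values)))
  if (!is.logical(mask) || !identical(dim(mask), dim(values)))
    stop("mask must be a logical matrix matching values")
  dimnames(mask) <- dimnames(values)
  values[!mask] <- NA_real_
  if (is.null(types)) {
    types <- vapply(seq_len(ncol(values)), function(j) {
      v <- values[mask[, j], j]
      if (length(v) > 0L && all(v %in% c(0, 1))) "binary" else "continuous"
    }, character(1))
  }
  types <- match.arg(types, c("binary", "continuous"), several.ok = TRUE)
  if (length(types) != ncol(values))
    stop("one type per column required")
  names(types) <- colnames(values)
  for (j in seq_len(ncol(values))) {
    v <- values[mask[, j], j]
    if (anyNA(v)) stop("observed cells must be non-missing")
    if (types[j] == "binary" && !all(v %in% c(0, 1)))
      stop("binary column ", colnames(values)[j],
           " contains observed values outside {0,1}")
  }
  if (!is.null(truth)) {
    truth <- as.matrix(truth)
    storage.mode(truth) <- "double"
    if (!identical(dim(truth), dim(values)))
      stop("truth must match values in shape")
    dimnames(truth) <- dimnames(values)
  }
  structure(list(values = values, mask = mask, types = types,
                 truth = truth),
            class = "md_dataset")
}

#' @export
print.md_dataset <- function(x, ...) {
  nmis <- colSums(!x$mask)
  cat(sprintf("md_dataset: %d subjects x %d variables\n",
              nrow(x$values), ncol(x$values)))
  for (j in seq_len(ncol(x$values)))
    cat(sprintf("  %-8s %-10s %4d missing\n", colnames(x$values)[j],
                x$types[j], nmis[j]))
  invisible(x)
}

#' @export
dim.md_dataset <- function(x) dim(x$values)

#' @export
as.data.frame.md_dataset <- function(x, ...) as.data.frame(x$values, ...)

is_complete <- function(data) all(data$mask)

#' Rows with every variable observed
#' @param data an [md_dataset].
#' @return logical vector, one entry per row.
#' @export
complete_rows <- function(data) rowSums(!data$mask) == 0L

#' Write / read a masked dataset as delimited text
#'
#' One row per subject, header row with column names, missing cells
#' written as the literal token `NA` (empty fields are also accepted on
#' read).
#'
#' @param data an [md_dataset].
#' @param path file path.
#' @export
write_md_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data$values), path, row.names = FALSE,
                   na = "NA")
  invisible(path)
}

#' @rdname write_md_csv
#' @param types optional explicit column types for [md_dataset].
#' @export
read_md_csv <- function(path, types = NULL) {
  df <- utils::read.csv(path, na.strings = c("NA", ""))
  md_dataset(as.matrix(df), types = types)
}
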