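#' Construct a CKD dataset object
#'
#' The central data container: a numeric feature matrix (categoricals already
#' coded), a parallel logical missingness mask, and a 0/1 label vector with
#' 1 = ckd (the positive class) and 0 = notckd. Masked cells hold `NA` in `X`
#' so they can never silently enter arithmetic.
#'
#' @param X numeric matrix, n x d (d = 24 for the standard schema).
#' @param mask logical matrix, same shape as `X`; `TRUE` marks a missing cell.
#' @param y integer/numeric vector of 0/1 labels, length n.
#' @param schema a `ckd_schema` describing the columns.
#' @param provenance one of `"uci"`, `"csv"`, `"synthetic"`.
#' @return An object of class `ckd_dataset`.
#' @export
ckd_dataset <- function(X, mask, y, schema = ckd_schema(),
                        provenance = c("csv", "uci", "synthetic")) {
  provenance <- match.arg(provenance)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  mask <- as.matrix(mask)
  if (!is.logical(mask)) stop("mask must be logical")
  if (!identical(dim(X), dim(mask)))
    stop("X and mask must have identical shape")
  if (nrow(X) < 1L) stop("dataset must have n >= 1 rows")
  if (ncol(X) != length(schema$names))
    stop("X must have ", length(schema$names), " columns, got ", ncol(X))
  y <- as.integer(y)
  if (length(y) != nrow(X)) stop("y length must equal nrow(X)")
  if (!all(y %in% c(0L, 1L))) stop("y must be coded {0, 1}")
  if (any(!is.na(X[mask]))) X[mask] <- NA_real_
  if (anyNA(X[!mask])) stop("observed cells must not be NA")
  colnames(X) <- schema$names
  colnames(mask) <- schema$names
  structure(list(X = X, mask = mask, y = y, schema = schema,
                 provenance = provenance),
            class = "ckd_dataset")
}

#' @export
print.ckd_dataset <- function(x, ...) {
  cat(sprintf("<ckd_dataset> %d patients x %d features (%s)\n",
              nrow(x$X), ncol(x$X), x$provenance))
  cat(sprintf("  labels: %d ckd, %d notckd; missing cells: %d (%.1f%%)\n",
              sum(x$y == 1L), sum(x$y == 0L), sum(x$mask),
              100 * mean(x$mask)))
  invisible(x)
}

#' @export
dim.ckd_dataset <- function(x) dim(x$X)

#' Subset the rows of a dataset
#'
#' @param ds a `ckd_dataset`
#' @param idx integer or logical row index
#' @return a `ckd_dataset` with the selected rows, order preserved.
#' @export
dataset_rows <- function(ds, idx) {
  ckd_dataset(ds$X[idx, , drop = FALSE], ds$mask[idx, , drop = FALSE],
              ds$y[idx], ds$schema, ds$provenance)
}

#' Field-for-field dataset equality
#' @param a,b `ckd_dataset` objects
#' @return TRUE/FALSE
#' @export
dataset_equal <- function(a, b) {
  isTRUE(all.equal(a$X, b$X)) && identical(a$mask, b$mask) &&
    identical(a$y, b$y) && identical(a$schema$names, b$schema$names)
}
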