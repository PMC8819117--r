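# ---- coverage-matrix post-processing ----------------------------------------

#' Reduce the 100-bin coverage matrix to 10 mean bins
#'
#' Column j (j = 0..9) of the reduced matrix is the arithmetic mean of source
#' columns 10j..10j+9. Values are averaged as-is, with no re-normalization in
#' 10-bin space: renormalizing would distort the relative amplitudes the
#' clustering relies on. Zero-coverage flags are carried through; flagged
#' rows stay all-zero.
#'
#' @param matrix A `coverage_matrix` (exactly 100 columns).
#' @return A `reduced_matrix`: list with `cell_ids`, `values` (n x 10),
#'   `bin_edges` (10 x 2 matrix of [start, end) position windows),
#'   `zero_flags`.
#' @export
reduce_bins <- function(matrix) {
  stopifnot(inherits(matrix, "coverage_matrix"))
  v <- matrix$values
  if (ncol(v) != 100L)
    stop("coverage matrix must have exactly 100 columns", call. = FALSE)
  grp <- rep(0:9, each = 10L)
  red <- t(apply(v, 1L, function(r) tapply(r, grp, mean)))
  if (nrow(v) == 1L) red <- base::matrix(red, nrow = 1L)
  rownames(red) <- matrix$cell_ids
  colnames(red) <- paste0("bin_", 0:9)
  structure(list(cell_ids = matrix$cell_ids,
                 values = red,
                 bin_edges = cbind(start = seq(0L, 90L, 10L),
                                   end = seq(10L, 100L, 10L)),
                 zero_flags = matrix$zero_flags),
            class = "reduced_matrix")
}

#' @export
print.reduced_matrix <- function(x, ...) {
  cat(sprintf("<reduced_matrix> %d cells x 10 bins (%d zero-coverage)\n",
              length(x$cell_ids), sum(x$zero_flags)))
  invisible(x)
}

# ---- TSV persistence ---------------------------------------------------------
#
# Dialect: header "cell_id" + pos_0..pos_99 (or bin_0..bin_9 for the reduced
# form), one row per cell, values with 6 decimals. CRLF input is accepted.

#' Write a coverage or reduced matrix to TSV
#' @param matrix A `coverage_matrix` or `reduced_matrix`.
#' @param path Output TSV path.
#' @export
save_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, c("coverage_matrix", "reduced_matrix")))
  v <- matrix$values
  dt <- data.table::data.table(cell_id = matrix$cell_ids)
  for (j in seq_len(ncol(v))) dt[[colnames(v)[j]]] <- sprintf("%.6f", v[, j])
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a coverage matrix from TSV
#'
#' Validates the dialect strictly: 100 position columns, numeric entries in
#' [0, 1], unique cell ids. Errors name the offending row and column.
#'
#' @param path TSV path (dialect of [save_matrix()]).
#' @return A `coverage_matrix`; rows whose values are all zero are flagged.
#' @export
load_matrix <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = "cell_id"),
                          data.table = TRUE)
  expected <- paste0("pos_", 0:99)
  if (!identical(names(dt), c("cell_id", expected)))
    stop("malformed coverage matrix header (want cell_id, pos_0..pos_99)",
         call. = FALSE)
  ids <- dt$cell_id
  if (anyDuplicated(ids))
    stop("duplicate cell_id: ", ids[duplicated(ids)][1L], call. = FALSE)
  v <- as.matrix(dt[, expected, with = FALSE])
  if (!is.numeric(v)) {
    bad <- which(!vapply(dt[, expected, with = FALSE], is.numeric, logical(1)))[1L]
    stop("non-numeric values in column ", expected[bad], call. = FALSE)
  }
  if (anyNA(v)) {
    w <- which(is.na(v), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing/non-numeric value at row %d (cell '%s'), column %s",
                 w[1L], ids[w[1L]], expected[w[2L]]), call. = FALSE)
  }
  if (any(v < 0 | v > 1)) {
    w <- which(v < 0 | v > 1, arr.ind = TRUE)[1L, ]
    stop(sprintf("value out of [0,1] at row %d (cell '%s'), column %s: %g",
                 w[1L], ids[w[1L]], expected[w[2L]], v[w[1L], w[2L]]),
         call. = FALSE)
  }
  new_coverage_matrix(ids, unname(v), zero_flags = rowSums(v) == 0)
}

#' Rows of a reduced matrix that enter clustering
#'
#' Zero-coverage cells never enter the trimmed fit; they are re-attached as
#' Skewed (reason `zero_coverage`) at labeling time.
#'
#' @param reduced A `reduced_matrix`.
#' @return List with `X` (rows for clustering), `ids`, `zero_ids`.
#' @export
clustering_input <- function(reduced) {
  stopifnot(inherits(reduced, "reduced_matrix"))
  keep <- !reduced$zero_flags
  list(X = reduced$values[keep, , drop = FALSE],
       ids = reduced$cell_ids[keep],
       zero_ids = reduced$cell_ids[!keep])
}
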