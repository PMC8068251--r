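#' Expression matrix container
#'
#' Light container pairing a sparse genes x cells count matrix with a
#' per-cell metadata tibble. This is the object the QC, normalisation and
#' cluster-summary steps operate on.
#'
#' @param counts A [Matrix::dgCMatrix] (or coercible matrix) with genes in
#'   rows and cells in columns. Dimnames are taken as gene symbols and cell
#'   ids when present.
#' @param cells A data frame with one row per cell. Must contain `cell_id`;
#'   typical extra columns are `sample`, `tissue` and `cluster`.
#' @param normalized Logical flag: `FALSE` for raw counts, `TRUE` after
#'   [normalize_counts()].
#'
#' @return An object of class `expr_matrix`: a list with elements `counts`
#'   (dgCMatrix), `cells` (tibble) and `normalized` (logical).
#' @export
expr_matrix <- function(counts, cells, normalized = FALSE) {
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  cells <- tibble::as_tibble(cells)
  if (!"cell_id" %in% names(cells)) {
    stop("`cells` must contain a `cell_id` column", call. = FALSE)
  }
  if (ncol(counts) != nrow(cells)) {
    stop("counts has ", ncol(counts), " columns but `cells` has ",
         nrow(cells), " rows", call. = FALSE)
  }
  if (anyDuplicated(cells$cell_id)) {
    stop("duplicated cell_id in `cells`", call. = FALSE)
  }
  if (is.null(rownames(counts))) {
    stop("counts must have gene symbols as rownames", call. = FALSE)
  }
  colnames(counts) <- cells$cell_id
  structure(
    list(counts = counts, cells = cells, normalized = isTRUE(normalized)),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("<expr_matrix> ", nrow(x$counts), " genes x ", ncol(x$counts), " cells",
      if (x$normalized) " (normalized)" else " (raw counts)", "\n", sep = "")
  if ("cluster" %in% names(x$cells)) {
    cat("  clusters: ", length(unique(x$cells$cluster)), "\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$counts)

#' Gene symbols of an expression matrix
#' @param x An `expr_matrix`.
#' @return Character vector of gene symbols.
#' @export
genes <- function(x) rownames(x$counts)

#' Write an expression matrix as a Matrix-Market triplet
#'
#' Writes `matrix.mtx` (1-based COO indices), `genes.tsv` (one symbol per
#' line) and `cells.tsv` (the cell metadata, tab-separated with header) into
#' `dir` -- the Cell-Ranger-style layout.
#'
#' @param x An `expr_matrix`.
#' @param dir Output directory, created if absent.
#' @return `dir`, invisibly.
#' @export
write_expression_mtx <- function(x, dir) {
  stopifnot(inherits(x, "expr_matrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(x$counts), file.path(dir, "genes.tsv"))
  readr::write_tsv(x$cells, file.path(dir, "cells.tsv"))
  invisible(dir)
}

#' Read an expression matrix from a Matrix-Market triplet
#'
#' @param dir Directory holding `matrix.mtx`, `genes.tsv`, `cells.tsv` as
#'   written by [write_expression_mtx()].
#' @return An `expr_matrix`.
#' @export
read_expression_mtx <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  g <- readLines(file.path(dir, "genes.tsv"))
  cells <- readr::read_tsv(file.path(dir, "cells.tsv"), show_col_types = FALSE)
  rownames(m) <- g
  expr_matrix(m, cells)
}
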