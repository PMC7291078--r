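#' Read an expression matrix
#'
#' Reads a dense delimited file (`.csv`/`.tsv`/`.txt`, first column = row
#' names, header = column names) or a Matrix Market `.mtx` file with
#' `genes.tsv` and `barcodes.tsv` sidecars in the same directory (the usual
#' genes x cells sparse layout). The returned dense matrix is oriented
#' cells x genes.
#'
#' @param path path to the matrix file.
#' @param orientation layout of the file on disk: `"cells_by_genes"` or
#'   `"genes_by_cells"`. Defaults to `"genes_by_cells"` for `.mtx` (the
#'   10x-style convention) and `"cells_by_genes"` for delimited files.
#' @return a numeric cells x genes matrix with cell and gene identifiers as
#'   dimnames.
#' @export
read_counts <- function(path, orientation = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "mtx") {
    orientation <- orientation %||% "genes_by_cells"
    m <- as.matrix(Matrix::readMM(path))
    dir <- dirname(path)
    genes_f <- file.path(dir, "genes.tsv")
    cells_f <- file.path(dir, "barcodes.tsv")
    if (file.exists(genes_f)) {
      g <- utils::read.delim(genes_f, header = FALSE, stringsAsFactors = FALSE)[[1L]]
      if (orientation == "genes_by_cells") rownames(m) <- g else colnames(m) <- g
    }
    if (file.exists(cells_f)) {
      b <- utils::read.delim(cells_f, header = FALSE, stringsAsFactors = FALSE)[[1L]]
      if (orientation == "genes_by_cells") colnames(m) <- b else rownames(m) <- b
    }
  } else {
    orientation <- orientation %||% "cells_by_genes"
    sep <- if (ext == "csv") "," else "\t"
    m <- as.matrix(utils::read.table(path, header = TRUE, sep = sep,
                                     row.names = 1L, check.names = FALSE))
  }
  orientation <- match.arg(orientation, c("cells_by_genes", "genes_by_cells"))
  if (orientation == "genes_by_cells") m <- t(m)
  storage.mode(m) <- "double"
  m
}

#' Write an expression matrix
#'
#' Writes a cells x genes matrix as dense CSV/TSV (with row and column
#' names) or as Matrix Market `.mtx` plus `genes.tsv`/`barcodes.tsv`
#' sidecars (stored genes x cells).
#'
#' @param x cells x genes matrix.
#' @param path output path; format chosen by extension (`.csv`, `.tsv`,
#'   `.mtx`).
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "mtx") {
    Matrix::writeMM(Matrix::Matrix(t(x), sparse = TRUE), path)
    dir <- dirname(path)
    writeLines(colnames(x) %||% paste0("gene", seq_len(ncol(x))),
               file.path(dir, "genes.tsv"))
    writeLines(rownames(x) %||% paste0("cell", seq_len(nrow(x))),
               file.path(dir, "barcodes.tsv"))
  } else {
    sep <- if (ext == "csv") "," else "\t"
    utils::write.table(x, path, sep = sep, quote = FALSE, col.names = NA)
  }
  invisible(path)
}

#' Save / load a fitted model
#'
#' Serializes the trained network (weights, architecture, variant, control
#' settings) to a single file and restores it; a round trip reproduces
#' forward passes exactly.
#'
#' @param model a `"scsdae_net"` or full `"scsdae"` fit.
#' @param path file path for the checkpoint.
#' @return `write_scsdae` returns `path` invisibly; `read_scsdae` returns
#'   the restored object.
#' @export
write_scsdae <- function(model, path) {
  stopifnot(inherits(model, c("scsdae", "scsdae_net")))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_scsdae
#' @export
read_scsdae <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, c("scsdae", "scsdae_net")))
    stop("not a saved scsdae model: ", path)
  obj
}
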