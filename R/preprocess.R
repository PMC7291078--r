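#' Remove unexpressed cells and genes
#'
#' Drops cells (rows) in which no gene is expressed and genes (columns)
#' expressed in no cell. Cells are filtered first, then genes; under
#' non-negative counts one pass of each is sufficient, but the filter is
#' applied repeatedly until stable as a safeguard. Retained row and column
#' names keep their original order, so the operation is idempotent.
#'
#' @param counts numeric matrix of non-negative expression values, cells in
#'   rows and genes in columns. Integer counts are typical, but non-integer
#'   intensities (e.g. microarray data) are accepted.
#' @return the filtered matrix, with `dimnames` preserved.
#' @examples
#' m <- rbind(c(0, 5), c(0, 0))
#' filter_matrix(m)  # 1 cell x 1 gene
#' @export
filter_matrix <- function(counts) {
  counts <- as_count_matrix(counts)
  repeat {
    keep_cells <- rowSums(counts > 0) > 0
    counts <- counts[keep_cells, , drop = FALSE]
    keep_genes <- colSums(counts > 0) > 0
    counts <- counts[, keep_genes, drop = FALSE]
    if (all(keep_cells) && all(keep_genes)) break
  }
  if (nrow(counts) == 0L || ncol(counts) == 0L)
    stop("no expressed cells/genes remain after filtering")
  counts
}

#' Library-size log normalization (logCPM)
#'
#' Scales each cell to counts per million and applies `log(. + 1)`:
#' `x_ij = log(count_ij / libsize_i * 1e6 + 1)`. Zero counts map exactly to
#' zero normalized values, so the zero pattern of the matrix is preserved.
#'
#' @param counts filtered non-negative matrix, cells in rows (every cell
#'   must have a positive library size; see [filter_matrix()]).
#' @param base base of the logarithm; natural log by default.
#' @return a numeric matrix of normalized values with attribute
#'   `"library_sizes"` holding the per-cell totals.
#' @examples
#' x <- normalize_cpm(rbind(c(1, 1, 2)))
#' exp(x) - 1  # CPM values: 250000 250000 500000
#' @export
normalize_cpm <- function(counts, base = exp(1)) {
  counts <- as_count_matrix(counts)
  lib <- rowSums(counts)
  if (any(lib <= 0))
    stop("unfiltered input: some cells have zero library size (run filter_matrix first)")
  x <- log1p(counts / lib * 1e6)
  if (base != exp(1)) x <- x / log(base)
  attr(x, "library_sizes") <- lib
  x
}

#' Observed-value mask
#'
#' Indicator of observed entries, `m_ij = I(x_ij > 0)`. `TRUE` entries are
#' treated as observed expression and preserved exactly by imputation;
#' `FALSE` entries (zeros) are imputation candidates.
#'
#' @param x normalized expression matrix.
#' @return a logical matrix of the same shape.
#' @export
zero_mask <- function(x) {
  m <- x > 0
  dimnames(m) <- dimnames(x)
  m
}

## coerce input to a plain dense matrix and validate non-negativity
as_count_matrix <- function(counts) {
  if (inherits(counts, "sparseMatrix")) counts <- as.matrix(counts)
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("'counts' must be a numeric matrix (cells x genes)")
  if (anyNA(counts)) stop("'counts' contains NA values")
  if (any(counts < 0)) stop("'counts' contains negative entries")
  counts
}
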