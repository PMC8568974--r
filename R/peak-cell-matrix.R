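#' Construct a peak-by-cell count matrix
#'
#' The central container of the package: a sparse non-negative integer
#' matrix of Tn5 insertion (cutting-site) counts with peaks as rows and
#' cells as columns, carrying the peak intervals and cell barcodes as
#' row/column metadata.
#'
#' @param counts A matrix coercible to [Matrix::sparseMatrix] (class
#'   `dgCMatrix`), peaks in rows, cells in columns. All stored values must
#'   be positive integers; explicit zeros are dropped at construction.
#' @param peaks A `data.frame` with columns `chrom`, `start`, `end`
#'   (0-based half-open intervals, unstranded) and one row per matrix row.
#' @param barcodes Character vector of unique cell identifiers, one per
#'   matrix column.
#'
#' @return An object of class `peak_cell_matrix`: a list with elements
#'   `counts` (`dgCMatrix`), `peaks`, `barcodes`.
#'
#' @examples
#' m <- Matrix::sparseMatrix(i = c(1, 3), j = c(1, 2), x = c(2, 1),
#'                           dims = c(3, 2))
#' pks <- data.frame(chrom = "chr1", start = c(0, 1000, 2000),
#'                   end = c(500, 1500, 2500))
#' pcm <- peak_cell_matrix(m, pks, c("AAAC", "AAAG"))
#' dim(pcm)
#' @export
peak_cell_matrix <- function(counts, peaks, barcodes) {
  counts <- as_dgc(counts)
  x <- counts@x
  if (length(x) && any(!is.finite(x)))
    stop("counts contain non-finite values", call. = FALSE)
  if (length(x) && any(x < 0))
    stop("counts contain negative values", call. = FALSE)
  if (length(x) && any(x != round(x)))
    stop("counts contain non-integer values", call. = FALSE)
  peaks <- validate_peaks(peaks, nrow(counts))
  barcodes <- as.character(barcodes)
  if (length(barcodes) != ncol(counts))
    stop(sprintf("barcode count (%d) does not match matrix columns (%d)",
                 length(barcodes), ncol(counts)), call. = FALSE)
  if (anyDuplicated(barcodes))
    stop("barcodes are not unique", call. = FALSE)
  rownames(counts) <- peak_ids(peaks)
  colnames(counts) <- barcodes
  structure(list(counts = counts, peaks = peaks, barcodes = barcodes),
            class = "peak_cell_matrix")
}

validate_peaks <- function(peaks, m) {
  peaks <- as.data.frame(peaks)
  need <- c("chrom", "start", "end")
  if (ncol(peaks) >= 3 && !all(need %in% names(peaks)))
    names(peaks)[1:3] <- need
  if (!all(need %in% names(peaks)))
    stop("peaks must have columns chrom, start, end", call. = FALSE)
  if (nrow(peaks) != m)
    stop(sprintf("peak count (%d) does not match matrix rows (%d)",
                 nrow(peaks), m), call. = FALSE)
  if (any(peaks$start >= peaks$end))
    stop("peak intervals must satisfy start < end", call. = FALSE)
  peaks
}

peak_ids <- function(peaks) {
  sprintf("%s:%d-%d", peaks$chrom, peaks$start, peaks$end)
}

#' @export
dim.peak_cell_matrix <- function(x) dim(x$counts)

#' @export
print.peak_cell_matrix <- function(x, ...) {
  nnz <- length(x$counts@x)
  cat(sprintf("peak_cell_matrix: %d peaks x %d cells, %d stored entries (%.2f%% non-zero)\n",
              nrow(x$counts), ncol(x$counts), nnz,
              100 * nnz / prod(dim(x$counts))))
  invisible(x)
}

#' @export
as.matrix.peak_cell_matrix <- function(x, ...) as.matrix(x$counts)

as_dgc <- function(x) {
  # promote pattern (ngC/ngT) and logical matrices to numeric storage
  if (is(x, "nsparseMatrix") || is(x, "lsparseMatrix"))
    x <- as(x, "dMatrix")
  Matrix::drop0(as(as(x, "CsparseMatrix"), "generalMatrix"))
}

as_counts <- function(x) {
  if (inherits(x, "peak_cell_matrix")) x$counts else as_dgc(x)
}
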