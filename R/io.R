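# Triplet (Matrix Market + BED + barcodes) reading and writing.
# Follows the 10x-style layout: matrix.mtx with 1-based coordinates,
# peaks.bed with 0-based half-open intervals, barcodes one per line.

open_text <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  magic <- readBin(path, "raw", n = 2L)
  if (length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b))
    gzfile(path, "rt")
  else
    file(path, "rt")
}

#' Read a sparse peak-by-cell matrix from the triplet layout
#'
#' Reads a Matrix Market coordinate file together with its BED peak and
#' barcode sidecars into a [peak_cell_matrix]. Row order follows the
#' peaks file, column order the barcodes file. Gzipped inputs are
#' detected by magic bytes.
#'
#' @param matrix_path Matrix Market (`.mtx`) coordinate file, 1-based
#'   indices, integer-valued entries.
#' @param peaks_path BED3+ file of peak intervals (0-based half-open).
#' @param barcodes_path Plain-text file, one cell barcode per line.
#'
#' @return A [peak_cell_matrix].
#' @export
read_peak_cell_matrix <- function(matrix_path, peaks_path, barcodes_path) {
  con <- open_text(matrix_path)
  on.exit(close(con), add = TRUE)
  mm <- Matrix::readMM(con)
  if (is(mm, "TsparseMatrix")) {
    key <- paste(mm@i, mm@j)
    if (anyDuplicated(key))
      stop(sprintf("matrix file contains %d duplicate (row,col) entries",
                   sum(duplicated(key))), call. = FALSE)
  }
  vals <- if (is(mm, "nsparseMatrix")) rep(1, length(mm@i)) else mm@x
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals != round(vals)))
    stop("matrix file contains negative or non-integer values", call. = FALSE)

  pcon <- open_text(peaks_path)
  on.exit(close(pcon), add = TRUE)
  peaks <- read.table(pcon, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE)
  if (ncol(peaks) < 3)
    stop("peaks file must have at least 3 tab-separated columns", call. = FALSE)
  names(peaks)[1:3] <- c("chrom", "start", "end")

  bcon <- open_text(barcodes_path)
  on.exit(close(bcon), add = TRUE)
  barcodes <- readLines(bcon)
  barcodes <- barcodes[nzchar(barcodes)]

  if (nrow(peaks) != nrow(mm))
    stop(sprintf("matrix header declares %d rows but peaks file has %d entries",
                 nrow(mm), nrow(peaks)), call. = FALSE)
  if (length(barcodes) != ncol(mm))
    stop(sprintf("matrix header declares %d columns but barcodes file has %d entries",
                 ncol(mm), length(barcodes)), call. = FALSE)

  peak_cell_matrix(mm, peaks, barcodes)
}

#' Write a matrix as Matrix Market or TSV
#'
#' @param x A matrix, sparse matrix, or [peak_cell_matrix].
#' @param path Output file path.
#' @param format `"mtx"` (1-based coordinate Matrix Market) or `"tsv"`
#'   (dense, barcode column headers, peak-id row labels).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  m <- if (inherits(x, "peak_cell_matrix")) x$counts else x
  vals <- if (is(m, "sparseMatrix")) as(m, "generalMatrix")@x else as.numeric(m)
  if (any(!is.finite(vals)))
    stop("matrix contains non-finite values; refusing to write", call. = FALSE)
  if (format == "mtx") {
    Matrix::writeMM(as(as(m, "CsparseMatrix"), "generalMatrix"), path)
  } else {
    dm <- as.matrix(m)
    df <- data.frame(peak = if (is.null(rownames(dm))) seq_len(nrow(dm)) else rownames(dm),
                     dm, check.names = FALSE, stringsAsFactors = FALSE)
    colnames(df) <- c("peak", if (is.null(colnames(dm))) paste0("cell_", seq_len(ncol(dm))) else colnames(dm))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Write a peak-by-cell matrix in the triplet layout
#'
#' Writes `matrix.mtx`, `peaks.bed` and `barcodes.tsv` under `dir`.
#'
#' @param x A [peak_cell_matrix].
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_peak_cell_matrix <- function(x, dir) {
  stopifnot(inherits(x, "peak_cell_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix(x$counts, file.path(dir, "matrix.mtx"), "mtx")
  bed <- x$peaks[, c("chrom", "start", "end")]
  write.table(bed, file.path(dir, "peaks.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  writeLines(x$barcodes, file.path(dir, "barcodes.tsv"))
  invisible(dir)
}
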