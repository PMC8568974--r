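# Binarize -> TF-IDF -> column L2 normalization: the transformation that
# turns raw insertion counts into the non-negative matrix V consumed by
# the factorization.

#' Filter sparsely observed peaks and cells
#'
#' Iteratively removes peaks open in fewer than `min_cells_per_peak`
#' cells and cells open in fewer than `min_peaks_per_cell` peaks until a
#' fixed point is reached (removing a cell can orphan a peak and vice
#' versa). The defaults are the minimum that keeps the TF-IDF weights
#' well-defined.
#'
#' @param x A [peak_cell_matrix].
#' @param min_cells_per_peak,min_peaks_per_cell Integer thresholds >= 1.
#' @return A filtered [peak_cell_matrix] with integer attributes
#'   `kept_peaks` and `kept_cells` giving the surviving indices relative
#'   to the input.
#' @export
filter_matrix <- function(x, min_cells_per_peak = 1L, min_peaks_per_cell = 1L) {
  stopifnot(min_cells_per_peak >= 1L, min_peaks_per_cell >= 1L)
  counts <- as_counts(x)
  bin <- counts
  bin@x <- rep(1, length(bin@x))
  keep_p <- seq_len(nrow(counts))
  keep_c <- seq_len(ncol(counts))
  repeat {
    rs <- Matrix::rowSums(bin)
    pk <- rs >= min_cells_per_peak
    if (any(!pk)) {
      bin <- bin[pk, , drop = FALSE]
      keep_p <- keep_p[pk]
    }
    cs <- Matrix::colSums(bin)
    ck <- cs >= min_peaks_per_cell
    if (any(!ck)) {
      bin <- bin[, ck, drop = FALSE]
      keep_c <- keep_c[ck]
    }
    if (all(pk) && all(ck)) break
    if (nrow(bin) == 0L || ncol(bin) == 0L)
      stop("filtering removed all peaks or all cells; lower the thresholds",
           call. = FALSE)
  }
  out <- if (inherits(x, "peak_cell_matrix")) {
    peak_cell_matrix(counts[keep_p, keep_c, drop = FALSE],
                     x$peaks[keep_p, , drop = FALSE],
                     x$barcodes[keep_c])
  } else {
    counts[keep_p, keep_c, drop = FALSE]
  }
  attr(out, "kept_peaks") <- keep_p
  attr(out, "kept_cells") <- keep_c
  out
}

#' Binarize a count matrix
#'
#' Maps any positive insertion count to 1 (peak open in that cell) and
#' zero to 0 (closed or dropped out). Downstream steps operate on this
#' open/closed indicator only; count magnitudes carry no signal at
#' scATAC-seq depth (at most ~2 insertions per site per cell).
#'
#' @param x A [peak_cell_matrix] or sparse non-negative matrix.
#' @return A sparse `dgCMatrix` with entries in \{0, 1\} and the same
#'   dimnames and sparsity pattern as the positive entries of `x`.
#' @export
binarize <- function(x) {
  counts <- as_counts(x)
  counts@x <- rep(1, length(counts@x))
  counts
}

#' TF-IDF weighting of a binary accessibility matrix
#'
#' Scores peak i in cell j as
#' \deqn{x''_{ij} = \frac{x'_{ij}}{\sum_p x'_{pj}}
#'       \log\!\left(\frac{n}{\sum_q x'_{iq}}\right)}
#' with natural log: the term frequency (1 over the cell's number of open
#' peaks) times the inverse document frequency (rarity of the peak across
#' the n cells). A peak open in every cell gets weight 0.
#'
#' @param bin Binary sparse matrix from [binarize()].
#' @return Sparse `dgCMatrix` of non-negative scores; the sparsity
#'   pattern is a subset of `bin`'s (ubiquitous peaks drop out).
#' @export
tfidf <- function(bin) {
  bin <- as_counts(bin)
  cs <- Matrix::colSums(bin)
  rs <- Matrix::rowSums(bin)
  if (any(cs == 0))
    stop(sprintf("%d cells have no open peaks; run filter_matrix() first",
                 sum(cs == 0)), call. = FALSE)
  if (any(rs == 0))
    stop(sprintf("%d peaks are open in no cell; run filter_matrix() first",
                 sum(rs == 0)), call. = FALSE)
  n <- ncol(bin)
  idf <- log(n / rs)
  out <- Matrix::Diagonal(x = idf) %*% bin %*% Matrix::Diagonal(x = 1 / cs)
  out <- Matrix::drop0(as(as(out, "CsparseMatrix"), "generalMatrix"))
  dimnames(out) <- dimnames(bin)
  out
}

#' L2-normalize the columns of a score matrix
#'
#' Divides every column by its Euclidean norm so each cell becomes a unit
#' vector; all-zero columns (cells open only in ubiquitous peaks) are
#' left as zeros with a warning, preserving cell indexing.
#'
#' @param scores Sparse non-negative matrix, e.g. from [tfidf()].
#' @return Sparse `dgCMatrix` whose nonzero columns have unit L2 norm.
#' @export
l2_normalize_columns <- function(scores) {
  scores <- as_counts(scores)
  if (length(scores@x) && any(!is.finite(scores@x) | scores@x < 0))
    stop("scores must be finite and non-negative", call. = FALSE)
  nrm <- sqrt(Matrix::colSums(scores^2))
  zero <- nrm == 0
  if (any(zero))
    warning(sprintf("%d all-zero columns left unnormalized", sum(zero)),
            call. = FALSE)
  nrm[zero] <- 1
  out <- scores %*% Matrix::Diagonal(x = 1 / nrm)
  out <- as(as(out, "CsparseMatrix"), "generalMatrix")
  dimnames(out) <- dimnames(scores)
  out
}

#' Preprocess counts into the normalized matrix V
#'
#' Composition `filter_matrix` -> [binarize()] -> [tfidf()] ->
#' [l2_normalize_columns()], producing the matrix V the factorization
#' approximates.
#'
#' @inheritParams filter_matrix
#' @return Sparse `dgCMatrix` V with unit-norm nonzero columns and
#'   attributes `kept_peaks`, `kept_cells` (indices into the input).
#' @export
preprocess <- function(x, min_cells_per_peak = 1L, min_peaks_per_cell = 1L) {
  filt <- filter_matrix(x, min_cells_per_peak, min_peaks_per_cell)
  v <- l2_normalize_columns(tfidf(binarize(filt)))
  attr(v, "kept_peaks") <- attr(filt, "kept_peaks")
  attr(v, "kept_cells") <- attr(filt, "kept_cells")
  v
}
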