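#' Fit the scOpen model to a peak-by-cell count matrix
#'
#' The main entry point: runs the full estimation pipeline on raw
#' insertion counts. Counts are filtered, binarized, TF-IDF weighted and
#' column L2-normalized into the matrix V ([preprocess()]); V is then
#' factorized as \eqn{V \approx WH} with non-negative factors by the
#' Frobenius-regularized NMF of [fit_nmf()]. With `rank = "auto"` the
#' rank is chosen by knee detection on an RSS curve over `rank_grid`
#' ([rss_curve()], [select_rank()]). `W %*% H` (via [fitted()] or
#' [impute()]) is the imputed accessibility matrix; `H` (via [coef()])
#' is the reduced cell embedding.
#'
#' @param x A [peak_cell_matrix], or any sparse non-negative count
#'   matrix with peaks in rows and cells in columns.
#' @param rank `"auto"` (default) or a positive integer.
#' @param lambda Regularization weight; default 1.
#' @param rank_grid Integer vector of candidate ranks for `"auto"`;
#'   default `2:30`.
#' @param max_sweeps,tol Solver controls, see [fit_nmf()].
#' @param min_cells_per_peak,min_peaks_per_cell Filtering thresholds,
#'   see [filter_matrix()].
#' @param seed Integer seed controlling factor initialization (and,
#'   via derived seeds, every fit on the rank grid).
#' @param verbose Print progress messages.
#'
#' @return An object of class `scopen`: a list with `W`, `H`, `k`,
#'   `lambda`, `objective`, `rss`, `converged`, `rank_curve` (an
#'   `rss_curve` or `NULL`), `v` (the normalized input, sparse),
#'   `kept_peaks`, `kept_cells`, `peaks`, `barcodes`, `seed`, `call`.
#'
#' @examples
#' sim <- simulate_cells(synth_bulk(m = 300, n_types = 3, seed = 1),
#'                       sim_config(cells_per_type = 40, seed = 1))
#' fit <- scopen(sim$counts, rank = 3, seed = 1)
#' fit
#' dim(coef(fit))       # 3 x n reduced embedding
#' m <- fitted(fit)     # imputed peaks x cells matrix
#' @export
scopen <- function(x, rank = "auto", lambda = 1, rank_grid = 2:30,
                   max_sweeps = 100L, tol = 1e-4,
                   min_cells_per_peak = 1L, min_peaks_per_cell = 1L,
                   seed = 42L, verbose = FALSE) {
  cl <- match.call()
  peaks <- if (inherits(x, "peak_cell_matrix")) x$peaks else NULL
  barcodes <- if (inherits(x, "peak_cell_matrix")) x$barcodes else colnames(as_counts(x))

  v <- preprocess(x, min_cells_per_peak, min_peaks_per_cell)
  kept_peaks <- attr(v, "kept_peaks")
  kept_cells <- attr(v, "kept_cells")
  if (!is.null(peaks)) peaks <- peaks[kept_peaks, , drop = FALSE]
  if (!is.null(barcodes)) barcodes <- barcodes[kept_cells]

  curve <- NULL
  if (identical(rank, "auto")) {
    if (verbose)
      message(sprintf("scanning rank grid [%d, %d] ...",
                      min(rank_grid), max(rank_grid)))
    curve <- rss_curve(v, ks = rank_grid, lambda = lambda,
                       max_sweeps = max_sweeps, tol = tol, seed = seed)
    rank <- select_rank(curve)
    curve$selected_k <- rank
    if (verbose) message(sprintf("selected rank k = %d", rank))
  }
  rank <- as.integer(rank)

  fit <- fit_nmf(v, k = rank, lambda = lambda, max_sweeps = max_sweeps,
                 tol = tol, seed = derive_seed(seed, rank))
  rownames(fit$W) <- rownames(v)
  colnames(fit$H) <- colnames(v)

  structure(list(W = fit$W, H = fit$H, k = rank, lambda = lambda,
                 objective = fit$objective, rss = fit$rss,
                 converged = fit$converged, rank_curve = curve,
                 v = v, kept_peaks = kept_peaks, kept_cells = kept_cells,
                 peaks = peaks, barcodes = barcodes,
                 seed = seed, call = cl),
            class = "scopen")
}

#' @export
print.scopen <- function(x, ...) {
  cat("scOpen regularized NMF fit\n")
  cat(sprintf("  V: %d peaks x %d cells (%d stored entries)\n",
              nrow(x$v), ncol(x$v), length(x$v@x)))
  cat(sprintf("  rank k = %d%s, lambda = %g\n", x$k,
              if (!is.null(x$rank_curve)) " (auto-selected)" else "",
              x$lambda))
  cat(sprintf("  %d sweeps (%s), RSS = %.6g\n", length(x$objective),
              if (x$converged) "converged" else "max sweeps reached",
              x$rss))
  invisible(x)
}

#' @export
summary.scopen <- function(object, ...) {
  out <- list(
    dims = dim(object$v),
    nnz = length(object$v@x),
    k = object$k,
    auto = !is.null(object$rank_curve),
    lambda = object$lambda,
    sweeps = length(object$objective),
    converged = object$converged,
    rss = object$rss,
    objective_final = object$objective[length(object$objective)],
    explained = 1 - object$rss / sum(object$v@x^2),
    h_range = range(object$H)
  )
  class(out) <- "summary.scopen"
  out
}

#' @export
print.summary.scopen <- function(x, ...) {
  cat("scOpen fit summary\n")
  cat(sprintf("  matrix: %d x %d, %d nonzeros (%.2f%%)\n", x$dims[1],
              x$dims[2], x$nnz, 100 * x$nnz / prod(x$dims)))
  cat(sprintf("  rank: %d%s   lambda: %g\n", x$k,
              if (x$auto) " (knee-selected)" else "", x$lambda))
  cat(sprintf("  solver: %d sweeps, %s\n", x$sweeps,
              if (x$converged) "converged" else "max sweeps reached"))
  cat(sprintf("  RSS: %.6g   fraction of ||V||^2 explained: %.3f\n",
              x$rss, x$explained))
  invisible(x)
}

#' Extract the reduced (cell embedding) or peak factor matrix
#'
#' @param object A fitted `scopen` model.
#' @param which `"H"` (default, the k x cells reduced matrix) or `"W"`
#'   (the peaks x k loadings).
#' @param ... Unused.
#' @export
coef.scopen <- function(object, which = c("H", "W"), ...) {
  which <- match.arg(which)
  object[[which]]
}

#' Imputed accessibility matrix of a fit
#'
#' @param object A fitted `scopen` model.
#' @param ... Passed to [impute()] (e.g. `max_gb`).
#' @return Dense peaks x cells matrix `W %*% H`.
#' @export
fitted.scopen <- function(object, ...) impute(object, ...)

#' @rdname fitted.scopen
#' @param newdata Unsupported; the model imputes the matrix it was fit
#'   on.
#' @export
predict.scopen <- function(object, newdata = NULL, ...) {
  if (!is.null(newdata))
    stop("scopen imputes the matrix it was fitted on; newdata is not supported",
         call. = FALSE)
  impute(object, ...)
}

#' Residuals of the factorization
#'
#' @param object A fitted `scopen` model.
#' @param ... Unused.
#' @return Dense matrix `V - W %*% H`.
#' @export
residuals.scopen <- function(object, ...) {
  as.matrix(object$v) - object$W %*% object$H
}

#' Diagnostic plots for a scopen fit
#'
#' Plots the per-sweep objective trace and, for auto-rank fits, the RSS
#' curve with the selected knee marked.
#'
#' @param x A fitted `scopen` model.
#' @param ... Passed to [graphics::plot.default].
#' @export
plot.scopen <- function(x, ...) {
  has_curve <- !is.null(x$rank_curve)
  if (has_curve) {
    op <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(op))
  }
  graphics::plot(seq_along(x$objective), x$objective, type = "b",
                 xlab = "sweep", ylab = "regularized objective",
                 main = sprintf("CCD trace (k = %d)", x$k), ...)
  if (has_curve) {
    graphics::plot(x$rank_curve$ks, x$rank_curve$rss, type = "b",
                   xlab = "rank k", ylab = "RSS", main = "rank selection")
    graphics::abline(v = x$k, lty = 2)
  }
  invisible(x)
}
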