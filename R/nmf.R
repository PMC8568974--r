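# Regularized NMF by cyclic coordinate descent, rank selection by knee
# detection on an RSS curve, and imputation as the factor product.

#' Closed-form coordinate update of the regularized NMF
#'
#' Solves the one-variable subproblem that cyclic coordinate descent
#' poses for a single factor entry: with the rest of the row fixed,
#' \deqn{\min_{z \ge 0} \sum_j (c_j + z h_{tj} - v_j)^2 + \frac{\lambda}{2} z^2}
#' where \eqn{c_j} is the current row prediction excluding coordinate
#' `t`. The minimizer is
#' \eqn{z^* = \max(0, \sum_j h_{tj}(v_j - c_j) / (\sum_j h_{tj}^2 + \lambda/2))}.
#' Exposed mainly for verification; the fitting loop runs the same rule
#' in compiled code with cached Gram matrices.
#'
#' @param v_row Numeric vector (length n): the data row being fit.
#' @param h Non-negative matrix (k x n): the fixed factor.
#' @param w_row Non-negative vector (length k): current row of the
#'   factor being updated.
#' @param t Coordinate index in `1:k` to update.
#' @param lambda Non-negative regularization weight.
#' @return The updated scalar value for `w_row[t]`.
#' @export
ccd_update <- function(v_row, h, w_row, t, lambda = 1) {
  stopifnot(is.matrix(h), length(w_row) == nrow(h),
            length(v_row) == ncol(h), t >= 1, t <= nrow(h), lambda >= 0)
  ht <- h[t, ]
  c_j <- drop(w_row %*% h) - w_row[t] * ht
  denom <- sum(ht^2) + lambda / 2
  if (denom == 0) return(0)
  max(0, sum(ht * (v_row - c_j)) / denom)
}

nmf_init <- function(m, n, k, v_mean, seed) {
  set.seed(seed)
  scale <- sqrt(max(v_mean, .Machine$double.eps) / k)
  list(W = matrix(runif(m * k), m, k) * scale,
       H = matrix(runif(k * n), k, n) * scale)
}

# deterministic per-rank seed so the RSS curve is reproducible and fits
# are independent across k
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483647)
}

#' Fit the regularized NMF at a fixed rank
#'
#' Minimizes \eqn{\sum_{ij} ((WH)_{ij} - v_{ij})^2 +
#' (\lambda/2)(\|W\|_F^2 + \|H\|_F^2)} over non-negative factors
#' \eqn{W (m \times k)}, \eqn{H (k \times n)} by cyclic coordinate
#' descent: each sweep updates every entry of W (rows, coordinates
#' 1..k) then every entry of H (columns) with the exact non-negative
#' one-variable minimizer, so the objective never increases. The loss
#' runs over all entries of V including zeros. Iteration stops when the
#' relative objective change drops below `tol` or after `max_sweeps`.
#'
#' @param v Sparse non-negative matrix V (e.g. from [preprocess()]).
#' @param k Positive integer rank, at most `min(dim(v))`.
#' @param lambda Non-negative regularization weight; default 1.
#' @param max_sweeps Maximum number of full W+H sweeps.
#' @param tol Relative objective-change stopping threshold.
#' @param seed Integer seed for the uniform random initialization
#'   (entries `runif` scaled by `sqrt(mean(v)/k)`).
#' @param init Optional list with matrices `W`, `H` to start from.
#' @return A list of class `nmf_factors`: `W`, `H`, `objective`
#'   (per-sweep trace of the regularized objective), `rss` (final
#'   residual sum of squares, regularization excluded), `converged`,
#'   `k`, `lambda`, `seed`.
#' @export
fit_nmf <- function(v, k, lambda = 1, max_sweeps = 100L, tol = 1e-4,
                    seed = 42L, init = NULL) {
  v <- as_counts(v)
  stopifnot(k >= 1, lambda >= 0, max_sweeps >= 1)
  if (k > min(dim(v)))
    stop(sprintf("rank k = %d exceeds min(dim(V)) = %d", k, min(dim(v))),
         call. = FALSE)
  if (length(v@x) && any(!is.finite(v@x) | v@x < 0))
    stop("V must be finite and non-negative", call. = FALSE)
  if (is.null(init)) {
    init <- nmf_init(nrow(v), ncol(v), k, sum(v@x) / prod(dim(v)), seed)
  }
  fit <- .ccd_fit_cpp(v, init$W, init$H, lambda, as.integer(max_sweeps), tol)
  structure(list(W = fit$W, H = fit$H, objective = fit$objective,
                 rss = fit$rss, converged = fit$converged,
                 k = as.integer(k), lambda = lambda, seed = seed),
            class = "nmf_factors")
}

#' @export
print.nmf_factors <- function(x, ...) {
  cat(sprintf("nmf_factors: rank %d, lambda %g, %d sweeps (%s), final objective %.6g\n",
              x$k, x$lambda, length(x$objective),
              if (x$converged) "converged" else "max sweeps reached",
              x$objective[length(x$objective)]))
  invisible(x)
}

#' Residual sum-of-squares curve over a rank grid
#'
#' Fits the NMF once per candidate rank and records the residual sum of
#' squares \eqn{\sum_{ij} (v_{ij} - (WH)_{ij})^2} (fit error only; the
#' regularization penalty is excluded so the curve reflects the
#' fit-error/complexity trade-off). Per-rank seeds are derived
#' deterministically from `seed` so fits are reproducible and
#' independent across the grid.
#'
#' @inheritParams fit_nmf
#' @param ks Integer vector of candidate ranks; the default grid is
#'   2 to 30. Ranks exceeding `min(dim(v))` are dropped with a warning.
#' @return A list of class `rss_curve`: `ks`, `rss`, and `selected_k`
#'   (`NA` until [select_rank()] is applied).
#' @export
rss_curve <- function(v, ks = 2:30, lambda = 1, max_sweeps = 100L,
                      tol = 1e-4, seed = 42L) {
  v <- as_counts(v)
  ks <- sort(unique(as.integer(ks)))
  stopifnot(length(ks) >= 1, all(ks >= 1))
  ok <- ks <= min(dim(v))
  if (!all(ok)) {
    warning(sprintf("rank grid truncated at min(dim(V)) = %d", min(dim(v))),
            call. = FALSE)
    ks <- ks[ok]
    if (!length(ks)) stop("no feasible ranks in grid", call. = FALSE)
  }
  rss <- vapply(ks, function(k) {
    fit_nmf(v, k, lambda = lambda, max_sweeps = max_sweeps, tol = tol,
            seed = derive_seed(seed, k))$rss
  }, numeric(1))
  structure(list(ks = ks, rss = rss, selected_k = NA_integer_),
            class = "rss_curve")
}

#' Select the rank at the knee of an RSS curve
#'
#' Min-max normalizes both axes to \[0, 1\] and returns the rank with
#' maximum perpendicular distance to the chord joining the curve's
#' endpoints — the standard knee construction trading fit error against
#' model complexity. Ties break toward the smallest rank.
#'
#' @param curve An `rss_curve` from [rss_curve()] (at least 3 points).
#' @return The selected integer rank.
#' @export
select_rank <- function(curve) {
  stopifnot(inherits(curve, "rss_curve"))
  ks <- curve$ks
  rss <- curve$rss
  if (length(ks) < 3)
    stop("need at least 3 grid points for knee detection; pass an explicit rank",
         call. = FALSE)
  x <- (ks - min(ks)) / (max(ks) - min(ks))
  yr <- max(rss) - min(rss)
  y <- if (yr > 0) (rss - min(rss)) / yr else rep(0, length(rss))
  # distance from (x_i, y_i) to the chord from (x_1, y_1) to (x_end, y_end);
  # endpoints sit on the chord, so only interior points are candidates
  dx <- x[length(x)] - x[1]
  dy <- y[length(y)] - y[1]
  d <- abs(dy * x - dx * y + dx * y[1] - dy * x[1]) / sqrt(dx^2 + dy^2)
  interior <- 2:(length(ks) - 1)
  ks[interior][which.max(d[interior])]  # first (smallest k) wins ties
}

#' Impute accessibility as the factor product
#'
#' Returns the dense matrix \eqn{M = WH}: the model's estimate of
#' open-chromatin propensity for every peak/cell pair, including pairs
#' observed as zero. No clipping or rescaling is applied; entries are
#' non-negative by construction.
#'
#' @param factors An `nmf_factors` object from [fit_nmf()] or a fitted
#'   [scopen] model.
#' @param max_gb Memory budget for the dense output, in GiB.
#' @return Dense numeric matrix, peaks x cells.
#' @export
impute <- function(factors, max_gb = 4) {
  W <- factors$W
  H <- factors$H
  stopifnot(!is.null(W), !is.null(H), ncol(W) == nrow(H))
  bytes <- 8 * as.numeric(nrow(W)) * ncol(H)
  if (bytes > max_gb * 2^30)
    stop(sprintf(paste0("dense imputed matrix would need %.1f GiB ",
                        "(budget %.1f); consider the reduced matrix H instead"),
                 bytes / 2^30, max_gb), call. = FALSE)
  W %*% H
}
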