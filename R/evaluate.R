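# Evaluation statistics: per-cell AUPR for dropout recovery, silhouette
# on 1-Pearson distance, adjusted Rand index, and the PCA +
# k-medoids/hierarchical clustering harness.

#' Area under the precision-recall curve
#'
#' Average-precision form with tie grouping: items are ranked by
#' descending score, tied scores are processed as one block, and the
#' area accumulates precision at each block weighted by the recall
#' gained there. Equals the step-function integral of the explicit PR
#' curve over all score thresholds.
#'
#' @param scores Numeric vector of predicted scores.
#' @param labels Binary vector (0/1 or logical) of the same length;
#'   must contain at least one positive and one negative.
#' @return A scalar in (0, 1\].
#' @export
aupr <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("AUPR undefined: need at least one positive and one negative label",
         call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  ends <- c(which(diff(s) != 0), length(s))        # last index of each tied block
  tp <- cumsum(l)[ends]
  precision <- tp / ends
  recall_gain <- diff(c(0, tp)) / n_pos
  sum(precision * recall_gain)
}

#' Per-cell recovery of true open regions
#'
#' Scores each cell's column of an (imputed or raw) matrix against the
#' ground-truth open peaks of that cell's type: peaks open in the type
#' are positives, the rest negatives, and the ranking quality is
#' summarized as AUPR.
#'
#' @param m Numeric matrix, peaks x cells (dense or sparse).
#' @param cell_labels Vector/factor of cell types, one per column.
#' @param true_open Logical matrix, peaks x types, with column names (or
#'   column order) matching the label levels.
#' @return Numeric vector of per-cell AUPR values.
#' @export
peak_recovery_aupr <- function(m, cell_labels, true_open) {
  cell_labels <- as.factor(cell_labels)
  stopifnot(ncol(m) == length(cell_labels), nrow(m) == nrow(true_open))
  cols <- if (!is.null(colnames(true_open)))
    match(levels(cell_labels), colnames(true_open))
  else seq_len(nlevels(cell_labels))
  if (anyNA(cols) || nlevels(cell_labels) > ncol(true_open))
    stop("cell type missing from true_open columns", call. = FALSE)
  vapply(seq_len(ncol(m)), function(j) {
    aupr(as.numeric(m[, j]), true_open[, cols[as.integer(cell_labels[j])]])
  }, numeric(1))
}

#' 1 - Pearson correlation distance between cells
#'
#' @param m Numeric matrix; distances are computed between columns.
#' @return A `dist`-convertible symmetric matrix of class
#'   `pearson_dist` with entries in \[0, 2\] and zero diagonal.
#'   Zero-variance columns get correlation 0 (distance 1) to every
#'   other column, with a warning.
#' @export
pearson_distance <- function(m) {
  m <- as.matrix(m)
  stopifnot(nrow(m) >= 2)
  sds <- apply(m, 2, stats::sd)
  cc <- suppressWarnings(cor(m))
  if (any(sds == 0)) {
    warning(sprintf("%d zero-variance columns assigned distance 1",
                    sum(sds == 0)), call. = FALSE)
    cc[is.na(cc)] <- 0
  }
  d <- 1 - cc
  diag(d) <- 0
  d[d < 0] <- 0  # guard fp noise
  structure(d, class = c("pearson_dist", "matrix"))
}

#' Silhouette widths on a distance matrix
#'
#' For each point x, \eqn{s(x) = (b(x) - a(x)) / \max(a(x), b(x))} where
#' a(x) is its mean distance to other members of its own class and b(x)
#' the smallest mean distance to another class. Members of singleton
#' classes get 0.
#'
#' @param d Symmetric distance matrix (or `dist`).
#' @param labels Class labels, one per row of `d`; at least 2 classes.
#' @return A list: `widths` (per-point vector), `mean`.
#' @export
silhouette_score <- function(d, labels) {
  d <- as.matrix(d)
  labels <- as.factor(labels)
  n <- nrow(d)
  stopifnot(length(labels) == n)
  if (nlevels(droplevels(labels)) < 2)
    stop("silhouette undefined for a single class", call. = FALSE)
  labels <- droplevels(labels)
  idx <- split(seq_len(n), labels)
  widths <- vapply(seq_len(n), function(i) {
    own <- idx[[as.integer(labels[i])]]
    own <- own[own != i]
    if (!length(own)) return(0)  # singleton class
    a <- mean(d[i, own])
    b <- min(vapply(idx[names(idx) != levels(labels)[as.integer(labels[i])]],
                    function(other) mean(d[i, other]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  list(widths = widths, mean = mean(widths))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement computed from the contingency table
#' \eqn{c_{ij} = |U_i \cap V_j|}: maximum 1 for identical partitions,
#' expectation 0 under random labelings. When the adjustment denominator
#' is 0 (both partitions trivial), identical partitions score 1.
#'
#' @param labels_u,labels_v Equal-length label vectors (length >= 2).
#' @return A scalar <= 1.
#' @export
adjusted_rand_index <- function(labels_u, labels_v) {
  if (length(labels_u) != length(labels_v))
    stop("label vectors differ in length", call. = FALSE)
  n <- length(labels_u)
  stopifnot(n >= 2)
  tab <- table(labels_u, labels_v)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  expected <- sum_a * sum_b / choose2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) {
    # both partitions trivial: identical iff the contingency table is
    # a permutation matrix on its nonzero pattern
    return(if (isTRUE(all.equal(sum_ij, max_index))) 1 else 0)
  }
  (sum_ij - expected) / (max_index - expected)
}

#' Cluster cells after PCA projection
#'
#' Centers features, projects cells onto the top principal components
#' (default 50, capped by the data dimensions), computes 1-Pearson
#' distance between cells in PC space, and partitions them with PAM
#' (k-medoids) or complete-linkage hierarchical clustering.
#'
#' @param m Numeric matrix, features x cells (imputed, reduced or raw).
#' @param n_clusters Number of clusters (<= number of cells).
#' @param method `"kmedoids"` (PAM) or `"hierarchical"` (complete
#'   linkage, cut at `n_clusters`).
#' @param n_pcs Number of principal components, default 50.
#' @param seed Integer seed (PAM medoid initialization).
#' @return Integer vector of cluster assignments, one per cell.
#' @export
cluster_cells <- function(m, n_clusters, method = c("kmedoids", "hierarchical"),
                          n_pcs = 50L, seed = 42L) {
  method <- match.arg(method)
  m <- as.matrix(m)
  n <- ncol(m)
  if (n_clusters > n)
    stop(sprintf("n_clusters (%d) exceeds number of cells (%d)",
                 n_clusters, n), call. = FALSE)
  if (n_clusters == 1L) return(rep(1L, n))
  npc <- min(n_pcs, n - 1L, nrow(m))
  pcs <- prcomp(t(m), center = TRUE, scale. = FALSE, rank. = npc)$x
  d <- pearson_distance(t(pcs))
  if (method == "kmedoids") {
    set.seed(seed)
    cluster::pam(as.dist(d), k = n_clusters, cluster.only = TRUE)
  } else {
    cutree(hclust(as.dist(d), method = "complete"), k = n_clusters)
  }
}

#' Evaluate an imputed matrix against ground-truth labels
#'
#' Bundles the package's evaluation protocol: per-cell AUPR against
#' true open regions (if truth is supplied), mean silhouette of the
#' known labels under 1-Pearson distance on the matrix, and the ARI
#' between a fresh clustering of the matrix and the known labels.
#'
#' @param m Numeric matrix, peaks x cells.
#' @param cell_labels Known cell labels, one per column.
#' @param true_open Optional logical peaks x types matrix for the AUPR
#'   protocol.
#' @param n_clusters Clusters for the harness; defaults to the number of
#'   label levels.
#' @inheritParams cluster_cells
#' @return A list of class `evaluation_report`: `per_cell_aupr` (or
#'   `NULL`), `mean_aupr`, `mean_silhouette`, `ari`, `cluster_labels`,
#'   `parameters`.
#' @export
evaluate_imputation <- function(m, cell_labels, true_open = NULL,
                                n_clusters = NULL,
                                method = c("kmedoids", "hierarchical"),
                                n_pcs = 50L, seed = 42L) {
  method <- match.arg(method)
  cell_labels <- as.factor(cell_labels)
  if (is.null(n_clusters)) n_clusters <- nlevels(cell_labels)
  per_cell <- if (!is.null(true_open))
    peak_recovery_aupr(m, cell_labels, true_open)
  sil <- silhouette_score(pearson_distance(as.matrix(m)), cell_labels)
  cl <- cluster_cells(m, n_clusters, method, n_pcs = n_pcs, seed = seed)
  structure(list(per_cell_aupr = per_cell,
                 mean_aupr = if (!is.null(per_cell)) mean(per_cell),
                 mean_silhouette = sil$mean,
                 ari = adjusted_rand_index(cl, cell_labels),
                 cluster_labels = cl,
                 parameters = list(n_clusters = n_clusters, method = method,
                                   n_pcs = n_pcs, seed = seed)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report\n")
  if (!is.null(x$mean_aupr))
    cat(sprintf("  mean per-cell AUPR: %.4f\n", x$mean_aupr))
  cat(sprintf("  mean silhouette:    %.4f\n", x$mean_silhouette))
  cat(sprintf("  ARI (%s, k = %d):   %.4f\n", x$parameters$method,
              x$parameters$n_clusters, x$ari))
  invisible(x)
}
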