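# Independent oracles used to pin conventions: each recomputes the
# quantity by brute force, never through the package's own code path.

# 1-D numeric minimizer of the CCD subproblem
#   f(z) = sum_j (c_j + z*h_j - v_j)^2 + (lambda/2) z^2,  z >= 0
ccd_oracle <- function(v, h_t, c_j, lambda, upper = 50) {
  f <- function(z) sum((c_j + z * h_t - v)^2) + lambda / 2 * z^2
  opt <- stats::optimize(f, c(0, upper), tol = 1e-12)
  # boundary z = 0 competes with the interior optimum
  if (f(0) <= opt$objective) 0 else opt$minimum
}

# Explicit PR-curve construction: confusion counts at every unique
# score threshold, step-function integration over recall.
aupr_oracle <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  thresholds <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels)
  prev_recall <- 0
  area <- 0
  for (th in thresholds) {
    pred <- scores >= th
    tp <- sum(pred & labels == 1)
    precision <- tp / sum(pred)
    recall <- tp / n_pos
    area <- area + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  area
}

# Pair-counting ARI: classify every element pair as co-clustered in
# both / one / neither partition, then adjust the Rand index.
ari_oracle <- function(u, v) {
  n <- length(u)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      su <- u[i] == u[j]
      sv <- v[i] == v[j]
      if (su && sv) n11 <- n11 + 1
      else if (su && !sv) n10 <- n10 + 1
      else if (!su && sv) n01 <- n01 + 1
      else n00 <- n00 + 1
    }
  }
  num <- 2 * (n11 * n00 - n10 * n01)
  den <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (den == 0) return(1)  # both partitions trivial and identical
  num / den
}

# All set partitions of 1..n as restricted-growth strings.
all_partitions <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  grow <- function(prefix) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(max(prefix) + 1L)) grow(c(prefix, v))
  }
  grow(1L)
  out
}

# small random sparse non-negative matrix
rand_sparse <- function(m, n, density = 0.1, seed = 1) {
  set.seed(seed)
  nnz <- max(1, round(m * n * density))
  idx <- sample(m * n, nnz)
  Matrix::sparseMatrix(i = (idx - 1) %% m + 1, j = (idx - 1) %/% m + 1,
                       x = runif(nnz), dims = c(m, n))
}

# tiny valid peak_cell_matrix fixture
toy_pcm <- function() {
  counts <- Matrix::sparseMatrix(i = c(1, 2, 3, 1), j = c(1, 1, 2, 2),
                                 x = c(2, 1, 1, 3), dims = c(3, 2))
  peaks <- data.frame(chrom = "chr1", start = c(0L, 1000L, 2000L),
                      end = c(500L, 1500L, 2500L))
  peak_cell_matrix(counts, peaks, c("AAAC", "AAAG"))
}
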