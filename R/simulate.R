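# Labelled scATAC-seq simulator: per-cell Bernoulli accessibility driven
# by cell-type-specific bulk rates mixed with uniform noise, sequencing
# depth drawn from a negative binomial and scaled by the fraction of
# reads in peaks (FRiP).

#' Simulation parameters
#'
#' Bundles the generative parameters of [simulate_cells()]. Defaults are
#' the study conditions used throughout the package: noise weight
#' `q = 0.6`, FRiP `f = 0.3`, 200 cells per type, negative-binomial
#' depth with mean 5000 and size 2.
#'
#' @param q Noise mixture weight in \[0, 1\]: fraction of a cell's reads
#'   falling uniformly across peaks rather than by its type's rates.
#' @param f Fraction of reads in peaks (FRiP), in (0, 1\].
#' @param cells_per_type Cells simulated per cell type.
#' @param nb_mean,nb_size Mean and dispersion size of the
#'   negative-binomial total read count per cell.
#' @param seed Integer seed.
#' @param clip_warn_fraction Warn when more than this fraction of
#'   Bernoulli probabilities had to be clipped to \[0, 1\].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(q = 0.6, f = 0.3, cells_per_type = 200L,
                       nb_mean = 5000, nb_size = 2, seed = 1L,
                       clip_warn_fraction = 0.01) {
  stopifnot(q >= 0, q <= 1, f > 0, f <= 1, cells_per_type >= 1,
            nb_mean > 0, nb_size > 0)
  structure(list(q = q, f = f, cells_per_type = as.integer(cells_per_type),
                 nb_mean = nb_mean, nb_size = nb_size,
                 seed = as.integer(seed),
                 clip_warn_fraction = clip_warn_fraction),
            class = "sim_config")
}

#' Generate a synthetic bulk accessibility profile
#'
#' Stands in for FACS-sorted bulk ATAC-seq counts: every peak gets a
#' Gamma-distributed baseline rate shared across cell types, and each
#' type additionally owns a disjoint block of marker peaks whose rate is
#' multiplied by `effect`. Columns are normalized to per-type rate
#' vectors summing to 1. Ground-truth open peaks per type are the type's
#' markers plus shared high-baseline peaks (above `open_quantile` of the
#' baseline).
#'
#' @param m Number of peaks.
#' @param n_types Number of cell types T.
#' @param marker_fraction Fraction of peaks assigned as markers to each
#'   type (disjoint blocks; `n_types * marker_fraction <= 1`).
#' @param effect Multiplicative rate increase on marker peaks (> 1).
#' @param baseline_shape Shape of the Gamma baseline (scale 1).
#' @param open_quantile Baseline quantile above which a peak counts as
#'   open in every type.
#' @param seed Integer seed.
#' @return A list of class `bulk_profile`: `rates` (m x T, columns sum
#'   to 1), `true_open` (m x T logical), `peak_ids`, `type_names`.
#' @export
synth_bulk <- function(m, n_types, marker_fraction = 0.05, effect = 8,
                       baseline_shape = 2, open_quantile = 0.9, seed = 1L) {
  stopifnot(m >= n_types, effect > 1, marker_fraction * m >= 1)
  n_marker <- floor(marker_fraction * m)
  if (n_marker * n_types > m)
    stop(sprintf(paste0("cannot assign %d disjoint markers to each of %d ",
                        "types with only %d peaks"),
                 n_marker, n_types, m), call. = FALSE)
  set.seed(seed)
  baseline <- rgamma(m, shape = baseline_shape, scale = 1)
  marker_idx <- split(seq_len(n_marker * n_types),
                      rep(seq_len(n_types), each = n_marker))
  rates <- matrix(baseline, m, n_types)
  true_open <- matrix(baseline >= stats::quantile(baseline, open_quantile),
                      m, n_types)
  for (t in seq_len(n_types)) {
    rates[marker_idx[[t]], t] <- rates[marker_idx[[t]], t] * effect
    true_open[marker_idx[[t]], t] <- TRUE
  }
  rates <- sweep(rates, 2, colSums(rates), "/")
  type_names <- paste0("type", seq_len(n_types))
  colnames(rates) <- colnames(true_open) <- type_names
  structure(list(rates = rates, true_open = true_open,
                 peak_ids = sprintf("peak_%05d", seq_len(m)),
                 type_names = type_names),
            class = "bulk_profile")
}

#' Simulate a labelled single-cell accessibility matrix
#'
#' For each cell j of type t, the total read count is
#' \eqn{N_j \sim \mathrm{NB}(\mathrm{size}, \mathrm{mean})}, the reads
#' in peaks \eqn{n_j = N_j f}, and peak i is open with probability
#' \deqn{p_i^t = r_i^t \, n_j (1-q) + \frac{n_j}{m} q,}
#' clipped to \[0, 1\], where \eqn{r_i^t} is the type's bulk rate.
#' Accessibility is drawn as independent Bernoulli per peak, so the
#' counts are binary by construction.
#'
#' @param bulk A `bulk_profile` from [synth_bulk()] (or a list with a
#'   column-normalized `rates` matrix and optional `true_open`).
#' @param config A [sim_config()].
#' @return A list of class `sim_scatac`: `counts` (a binary
#'   [peak_cell_matrix] with synthetic coordinates), `cell_labels`
#'   (factor, one type per cell), `true_open` (m x T logical),
#'   `n_clipped` (number of probabilities clipped), `config`.
#' @export
simulate_cells <- function(bulk, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  r <- bulk$rates
  if (any(abs(colSums(r) - 1) > 1e-8))
    stop("bulk rate columns must sum to 1", call. = FALSE)
  m <- nrow(r)
  n_types <- ncol(r)
  n_cells <- n_types * config$cells_per_type
  set.seed(config$seed)

  N <- rnbinom(n_cells, size = config$nb_size, mu = config$nb_mean)
  n_in_peaks <- N * config$f
  types <- rep(seq_len(n_types), each = config$cells_per_type)

  ii <- vector("list", n_cells)
  n_clipped <- 0L
  for (j in seq_len(n_cells)) {
    p <- r[, types[j]] * n_in_peaks[j] * (1 - config$q) +
      n_in_peaks[j] * config$q / m
    n_clipped <- n_clipped + sum(p > 1)
    p[p > 1] <- 1
    ii[[j]] <- which(runif(m) < p)
  }
  lens <- lengths(ii)
  counts <- Matrix::sparseMatrix(i = unlist(ii),
                                 j = rep.int(seq_len(n_cells), lens),
                                 x = 1, dims = c(m, n_cells))
  clip_frac <- n_clipped / (as.numeric(m) * n_cells)
  if (clip_frac > config$clip_warn_fraction)
    warning(sprintf("%.2f%% of Bernoulli probabilities clipped to 1",
                    100 * clip_frac), call. = FALSE)

  peaks <- data.frame(chrom = "chr1",
                      start = (seq_len(m) - 1L) * 1000L,
                      end = (seq_len(m) - 1L) * 1000L + 500L)
  barcodes <- sprintf("cell_%05d", seq_len(n_cells))
  labels <- factor(bulk$type_names[types] %||% paste0("type", types),
                   levels = bulk$type_names %||% paste0("type", seq_len(n_types)))
  structure(list(counts = peak_cell_matrix(counts, peaks, barcodes),
                 cell_labels = labels,
                 true_open = bulk$true_open,
                 n_clipped = n_clipped,
                 config = config),
            class = "sim_scatac")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sim_scatac <- function(x, ...) {
  cat(sprintf("sim_scatac: %d peaks x %d cells, %d types, q = %g, f = %g\n",
              nrow(x$counts$counts), ncol(x$counts$counts),
              nlevels(x$cell_labels), x$config$q, x$config$f))
  invisible(x)
}

#' Probability that an accessible site shows no event
#'
#' Under a binomial capture model, a site hit by `n_fragments`
#' independent fragments each surviving the protocol with probability
#' `p_capture` yields no observed event — a dropout — with probability
#' \eqn{(1 - p)^n}. With at most 2 fragments per open site and 25%
#' capture this gives 0.5625, i.e. over half of accessible sites drop
#' out.
#'
#' @param p_capture Per-fragment capture probability in \[0, 1\].
#' @param n_fragments Number of fragments generated at the site.
#' @return The dropout probability.
#' @examples
#' expected_dropout_rate(0.25, 2)  # 0.5625
#' @export
expected_dropout_rate <- function(p_capture, n_fragments = 2L) {
  if (any(p_capture < 0 | p_capture > 1))
    stop("p_capture must be in [0, 1]", call. = FALSE)
  if (any(n_fragments < 0))
    stop("n_fragments must be >= 0", call. = FALSE)
  (1 - p_capture)^n_fragments
}

#' Fraction of fragments carrying two distinct adapters
#'
#' Tn5 loads one of two adapter species independently and uniformly onto
#' each end of a fragment; only fragments with two distinct adapters
#' amplify in PCR. Enumerates the four equally likely end assignments
#' and returns the distinct-adapter fraction (1/2).
#'
#' @param n_adapters Number of adapter species (2 for standard ATAC-seq).
#' @return Probability that the two ends carry different adapters.
#' @examples
#' distinct_adapter_fraction()  # 0.5
#' @export
distinct_adapter_fraction <- function(n_adapters = 2L) {
  stopifnot(n_adapters >= 1)
  ends <- expand.grid(end1 = seq_len(n_adapters), end2 = seq_len(n_adapters))
  mean(ends$end1 != ends$end2)
}
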