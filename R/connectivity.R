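# Per-subject functional connectivity: Pearson correlation matrices, their
# Fisher-z transform, and binarization into undirected graphs over a
# threshold grid.

#' Pearson connectivity matrix of a time series
#'
#' @param ts A time x N matrix with at least 3 rows and no constant column.
#' @param subject_id Optional identifier carried on the result.
#' @return A list of class `"connectivity"` with elements `r` (N x N Pearson
#'   correlations, unit diagonal), `z` (Fisher r-to-z, `atanh(r)`
#'   off-diagonal, `NA` on the diagonal) and `subject_id`.
#' @export
correlation_matrix <- function(ts, subject_id = NULL) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3) abort("need at least 3 time points")
  sds <- apply(ts, 2, sd)
  if (any(sds == 0)) {
    nm <- colnames(ts) %||% as.character(seq_len(ncol(ts)))
    abort(paste0("constant time series for ROI: ",
                 paste(nm[sds == 0], collapse = ", ")))
  }
  r <- cor(ts)
  z <- suppressWarnings(atanh(pmin(pmax(r, -1), 1)))
  diag(z) <- NA_real_
  structure(list(r = r, z = z, subject_id = subject_id),
            class = "connectivity")
}

#' Fisher r-to-z transform
#'
#' `atanh(r)`: odd, strictly increasing, variance-stabilising for sample
#' correlations.
#'
#' @param r Correlation value(s) with `|r| < 1`.
#' @return `atanh(r)`.
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1)) {
    abort("fisher_z requires |r| < 1")
  }
  atanh(r)
}

#' Binarize a connectivity matrix at a correlation threshold
#'
#' An undirected, self-loop-free graph: edge `(i, j)` exists exactly when
#' `r_ij >= T` (signed comparison; negative correlations never form edges at
#' positive thresholds unless `abs_threshold = TRUE`).
#'
#' @param conn A `"connectivity"` object or a plain correlation matrix.
#' @param threshold Correlation cutoff `T` in (-1, 1).
#' @param abs_threshold Compare `|r|` instead of `r` (sensitivity analyses;
#'   default `FALSE`).
#' @return A 0/1 integer matrix of class `"binary_graph"` with zero diagonal
#'   and attribute `threshold`.
#' @export
binarize <- function(conn, threshold, abs_threshold = FALSE) {
  r <- if (inherits(conn, "connectivity")) conn$r else as.matrix(conn)
  if (threshold <= -1 || threshold >= 1) {
    abort("threshold must lie in (-1, 1)")
  }
  v <- if (abs_threshold) abs(r) else r
  adj <- (v >= threshold) * 1L
  diag(adj) <- 0L
  mode(adj) <- "integer"
  structure(adj, threshold = threshold, class = c("binary_graph", class(adj)))
}

#' Equally spaced correlation-threshold grid
#'
#' Defaults to 25 thresholds from 0.05 to 0.30, endpoints included.
#'
#' @param lo,hi Grid endpoints, `lo < hi`.
#' @param steps Number of thresholds (at least 2).
#' @return Numeric vector of length `steps`.
#' @export
threshold_grid <- function(lo = 0.05, hi = 0.3, steps = 25L) {
  steps <- as.integer(steps)
  if (!(lo < hi)) abort("need lo < hi")
  if (steps < 2) abort("need at least 2 steps")
  seq(lo, hi, length.out = steps)
}

#' Average nodal signal of a network
#'
#' Row-wise mean of the time series over the requested network's ROIs; used
#' for the internetwork (SN vs CEN) connectivity comparison.
#'
#' @param ts A time x N matrix, columns in atlas order.
#' @param atlas Atlas tibble.
#' @param network `"SN"`, `"CEN"` or `"ALL"`.
#' @return A numeric vector of length `nrow(ts)`.
#' @export
average_network_signal <- function(ts, atlas = sn_cen_atlas(),
                                   network = c("SN", "CEN", "ALL")) {
  network <- match.arg(network)
  ts <- as.matrix(ts)
  if (ncol(ts) != nrow(atlas)) abort("ts must have one column per atlas ROI")
  idx <- network_indices(atlas, network)
  rowMeans(ts[, idx, drop = FALSE])
}
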