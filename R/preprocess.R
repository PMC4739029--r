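# Desk-scale cleaning of ROI time series: initial-volume discard, zero-phase
# band-pass filtering, and nuisance regression. Scanner-level steps (slice
# timing, motion correction, spatial normalisation, smoothing) are out of
# scope; inputs are assumed already in MNI space.

#' Discard the first k volumes of a time series
#'
#' @param ts A time x K numeric matrix.
#' @param k Number of initial rows to drop (default 5, matching the
#'   convention of discarding pre-equilibrium volumes).
#' @return The matrix without its first `k` rows.
#' @export
discard_initial_volumes <- function(ts, k = 5L) {
  ts <- as.matrix(ts)
  k <- as.integer(k)
  if (k < 0) abort("k must be non-negative")
  if (nrow(ts) <= k) {
    abort(sprintf("cannot discard %d volumes from a %d-row series", k, nrow(ts)))
  }
  if (k == 0L) return(ts)
  ts[-seq_len(k), , drop = FALSE]
}

#' Zero-phase band-pass filter, column-wise
#'
#' Removes each column's mean, then applies a 4th-order Butterworth band-pass
#' forward and backward (zero phase). The defaults keep 0.01-0.08 Hz, the
#' band conventionally retained in resting-state analyses. Sinusoids inside
#' the band retain at least 90% of their amplitude; sinusoids at or below
#' half the low cutoff, or at or above twice the high cutoff, retain at most
#' 10%.
#'
#' @param ts A time x K numeric matrix.
#' @param tr_seconds Sampling interval (seconds); the sampling rate is
#'   `1 / tr_seconds`.
#' @param low_hz,high_hz Band edges in Hz; `high_hz` must be below the
#'   Nyquist frequency `1 / (2 * tr_seconds)`.
#' @param order Butterworth order (default 4).
#' @return The filtered matrix (column means removed), same dimnames.
#' @export
bandpass_filter <- function(ts, tr_seconds, low_hz = 0.01, high_hz = 0.08,
                            order = 4L) {
  ts <- as.matrix(ts)
  if (tr_seconds <= 0) abort("tr_seconds must be positive")
  nyquist <- 1 / (2 * tr_seconds)
  if (low_hz <= 0 || low_hz >= high_hz) {
    abort("need 0 < low_hz < high_hz")
  }
  if (high_hz >= nyquist) {
    abort(sprintf("high_hz (%.3g Hz) must be below the Nyquist frequency %.3g Hz",
                  high_hz, nyquist))
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / nyquist, type = "pass")
  centred <- scale(ts, center = TRUE, scale = FALSE)
  out <- apply(centred, 2, function(col) signal::filtfilt(bf, col))
  out <- matrix(out, nrow = nrow(ts), ncol = ncol(ts))
  dimnames(out) <- dimnames(ts)
  out
}

#' Regress nuisance signals out of every column
#'
#' Each column of `ts` is replaced by its least-squares residual against an
#' intercept plus the nuisance regressors, so residuals are orthogonal to
#' every regressor. The canonical nuisance set has 9 columns: white-matter
#' mean, CSF mean, global signal, 3 rotations and 3 translations.
#'
#' @param ts A time x N numeric matrix.
#' @param nuisance A time x Q numeric matrix with the same number of rows.
#' @return The residual matrix, same dimnames as `ts`.
#' @export
nuisance_regress <- function(ts, nuisance) {
  ts <- as.matrix(ts)
  nuisance <- as.matrix(nuisance)
  if (nrow(nuisance) != nrow(ts)) {
    abort("nuisance must have the same number of rows as the time series")
  }
  design <- cbind(intercept = 1, nuisance)
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    dropped <- colnames(design)[qr_d$pivot[(qr_d$rank + 1):ncol(design)]]
    abort(paste0("nuisance design is rank deficient; collinear columns: ",
                 paste(dropped, collapse = ", ")))
  }
  out <- qr.resid(qr_d, ts)
  dimnames(out) <- dimnames(ts)
  out
}

#' Full per-subject cleaning pipeline
#'
#' Applies, in order: initial-volume discard, band-pass filter, nuisance
#' regression (skipped with a message when `nuisance` is `NULL`, as for
#' synthetic ROI input with no scanner nuisances). The alternative
#' regress-before-filter order is available via `order`.
#'
#' @param ts A time x N matrix.
#' @param tr_seconds Sampling interval in seconds.
#' @param discard Initial volumes to drop (default 5).
#' @param low_hz,high_hz Band-pass edges (defaults 0.01 and 0.08 Hz).
#' @param nuisance Optional time x Q nuisance matrix, aligned with the
#'   *original* (pre-discard) series; its first `discard` rows are dropped
#'   in step.
#' @param order `"filter_first"` (default) or `"regress_first"`.
#' @param bandpass Set `FALSE` to skip filtering.
#' @return The cleaned time x N matrix.
#' @export
preprocess_subject <- function(ts, tr_seconds, discard = 5L,
                               low_hz = 0.01, high_hz = 0.08,
                               nuisance = NULL,
                               order = c("filter_first", "regress_first"),
                               bandpass = TRUE) {
  order <- match.arg(order)
  out <- discard_initial_volumes(ts, discard)
  if (!is.null(nuisance)) {
    nuisance <- discard_initial_volumes(as.matrix(nuisance), discard)
  }
  do_filter <- function(x) {
    if (bandpass) bandpass_filter(x, tr_seconds, low_hz, high_hz) else x
  }
  do_regress <- function(x) {
    if (is.null(nuisance)) {
      message("no nuisance regressors supplied; skipping nuisance regression")
      x
    } else {
      nuisance_regress(x, nuisance)
    }
  }
  if (order == "filter_first") do_regress(do_filter(out)) else do_filter(do_regress(out))
}
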