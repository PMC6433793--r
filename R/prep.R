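# Time-series conditioning applied before network construction, mirroring the
# usual resting-state pipeline at the ROI level: drop dummy volumes, remove
# linear drift, band-pass to the low-frequency BOLD band, regress nuisance
# signals.

#' Discard initial volumes
#'
#' Removes the first \code{n_discard} timepoints (scanner equilibration
#' volumes) from an ROI time series.
#'
#' @param ts \code{roi_timeseries}.
#' @param n_discard non-negative count, strictly less than the number of rows.
#' @return \code{roi_timeseries} with \code{T - n_discard} rows.
#' @export
discard_initial <- function(ts, n_discard = 10L) {
  stopifnot(inherits(ts, "roi_timeseries"))
  n_discard <- as.integer(n_discard)
  if (n_discard < 0L) stop("n_discard must be non-negative")
  if (n_discard >= nrow(ts$data))
    stop("n_discard (", n_discard, ") must be smaller than the number of timepoints (",
         nrow(ts$data), ")")
  if (n_discard == 0L) return(ts)
  roi_timeseries(ts$data[-seq_len(n_discard), , drop = FALSE],
                 tr_seconds = ts$tr_seconds, subject_id = ts$subject_id,
                 roi_labels = ts$roi_labels)
}

#' Remove linear drift
#'
#' Subtracts the per-column least-squares line (intercept + slope * time),
#' so each output column has zero fitted trend. Idempotent.
#'
#' @param ts \code{roi_timeseries} with at least 3 timepoints.
#' @return Detrended \code{roi_timeseries}.
#' @export
detrend_linear <- function(ts) {
  stopifnot(inherits(ts, "roi_timeseries"))
  tt <- nrow(ts$data)
  if (tt < 3L) stop("need at least 3 timepoints to detrend")
  X <- cbind(1, seq_len(tt))
  fit <- X %*% qr.coef(qr(X), ts$data)
  roi_timeseries(ts$data - fit, tr_seconds = ts$tr_seconds,
                 subject_id = ts$subject_id, roi_labels = ts$roi_labels)
}

#' Band-pass filter
#'
#' Zero-phase frequency-domain filter keeping components with frequency in
#' [low_hz, high_hz] (default 0.01-0.08 Hz, the low-frequency BOLD band).
#' Implemented by zeroing DFT bins outside the band, which is exactly
#' zero-phase and introduces no inter-column lag; the mean (0 Hz) is removed.
#'
#' @param ts \code{roi_timeseries}.
#' @param low_hz,high_hz band edges; 0 < low_hz < high_hz < 1/(2 TR).
#' @return Filtered \code{roi_timeseries}.
#' @export
bandpass <- function(ts, low_hz = 0.01, high_hz = 0.08) {
  stopifnot(inherits(ts, "roi_timeseries"))
  nyq <- 1 / (2 * ts$tr_seconds)
  if (!(low_hz > 0 && low_hz < high_hz)) stop("need 0 < low_hz < high_hz")
  if (high_hz >= nyq)
    stop("high_hz (", high_hz, " Hz) must be below the Nyquist frequency (",
         nyq, " Hz)")
  tt <- nrow(ts$data)
  if (tt < 30L) stop("need at least 30 timepoints for stable filtering")
  freq <- (seq_len(tt) - 1) / (tt * ts$tr_seconds)
  freq <- pmin(freq, 1 / ts$tr_seconds - freq)  # fold to [0, Nyquist]
  keep <- freq >= low_hz & freq <= high_hz
  out <- Re(stats::mvfft(stats::mvfft(ts$data) * keep, inverse = TRUE)) / tt
  roi_timeseries(out, tr_seconds = ts$tr_seconds,
                 subject_id = ts$subject_id, roi_labels = ts$roi_labels)
}

#' Regress out nuisance signals
#'
#' Projects each ROI column onto the orthogonal complement of the column
#' space of \code{nuisance} (head-motion parameters, global mean signal, ...).
#' An intercept is NOT added implicitly; include a column of ones to demean.
#'
#' @param ts \code{roi_timeseries}.
#' @param nuisance numeric T x K matrix of nuisance regressors.
#' @return Residual \code{roi_timeseries}, orthogonal to every nuisance column.
#' @export
regress_nuisance <- function(ts, nuisance) {
  stopifnot(inherits(ts, "roi_timeseries"))
  nuisance <- as.matrix(nuisance)
  if (nrow(nuisance) != nrow(ts$data))
    stop("nuisance rows must match the number of timepoints")
  if (ncol(nuisance) >= nrow(ts$data)) stop("more nuisance regressors than timepoints")
  if (any(!is.finite(nuisance))) stop("nuisance regressors must be finite")
  qrn <- qr(nuisance)
  if (qrn$rank < ncol(nuisance)) {
    warning("rank-deficient nuisance matrix; using pseudo-inverse projection")
    sv <- svd(nuisance)
    pos <- sv$d > max(dim(nuisance)) * .Machine$double.eps * sv$d[1]
    U <- sv$u[, pos, drop = FALSE]
    fit <- U %*% (t(U) %*% ts$data)
  } else {
    fit <- nuisance %*% qr.coef(qrn, ts$data)
  }
  roi_timeseries(ts$data - fit, tr_seconds = ts$tr_seconds,
                 subject_id = ts$subject_id, roi_labels = ts$roi_labels)
}

#' Standard conditioning pipeline
#'
#' Convenience composition: discard initial volumes, detrend, band-pass,
#' then (optionally) regress nuisance covariates — in that order.
#'
#' @param ts \code{roi_timeseries}.
#' @param n_discard initial volumes to drop (default 10).
#' @param low_hz,high_hz band-pass edges (defaults 0.01 and 0.08 Hz).
#' @param nuisance optional T x K nuisance matrix (T after discarding).
#' @return Conditioned \code{roi_timeseries}.
#' @export
prep_timeseries <- function(ts, n_discard = 10L, low_hz = 0.01, high_hz = 0.08,
                            nuisance = NULL) {
  out <- discard_initial(ts, n_discard)
  out <- detrend_linear(out)
  out <- bandpass(out, low_hz, high_hz)
  if (!is.null(nuisance)) out <- regress_nuisance(out, nuisance)
  out
}
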