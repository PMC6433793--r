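#' ROI time-series container
#'
#' One subject's regional BOLD signals: a T x N numeric matrix (T timepoints,
#' N regions of interest) plus the sampling interval (TR) in seconds.
#'
#' @param data numeric T x N matrix, no missing values.
#' @param tr_seconds positive scalar sampling interval.
#' @param subject_id character label.
#' @param roi_labels character vector of length N; defaults to the matrix
#'   column names or \code{V1..VN}.
#' @return An object of class \code{roi_timeseries}.
#' @export
roi_timeseries <- function(data, tr_seconds = 2, subject_id = "subject",
                           roi_labels = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (anyNA(data) || any(!is.finite(data)))
    stop("time-series matrix contains missing or non-finite values")
  if (nrow(data) < 2L) stop("need at least 2 timepoints")
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L || tr_seconds <= 0)
    stop("tr_seconds must be a positive scalar")
  if (is.null(roi_labels)) {
    roi_labels <- colnames(data)
    if (is.null(roi_labels)) roi_labels <- paste0("V", seq_len(ncol(data)))
  }
  if (length(roi_labels) != ncol(data))
    stop("roi_labels length (", length(roi_labels),
         ") does not match number of columns (", ncol(data), ")")
  colnames(data) <- roi_labels
  structure(list(data = data, tr_seconds = as.numeric(tr_seconds),
                 subject_id = as.character(subject_id),
                 roi_labels = as.character(roi_labels)),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat("<roi_timeseries> subject:", x$subject_id,
      sprintf("| %d timepoints x %d ROIs | TR = %gs\n",
              nrow(x$data), ncol(x$data), x$tr_seconds))
  invisible(x)
}

#' @export
dim.roi_timeseries <- function(x) dim(x$data)

#' Weighted functional connection matrix
#'
#' Symmetric N x N Pearson correlation matrix between ROI time series, unit
#' diagonal. The diagonal is carried but excluded from every edge operation.
#'
#' @param weights symmetric numeric matrix with values in [-1, 1].
#' @param roi_labels character labels, one per row/column.
#' @return An object of class \code{connectivity_matrix}.
#' @export
connectivity_matrix <- function(weights, roi_labels = NULL) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (ncol(weights) != n) stop("weights must be square")
  if (max(abs(weights - t(weights))) > 1e-8) stop("weights must be symmetric")
  weights <- (weights + t(weights)) / 2
  if (any(weights < -1 - 1e-8) || any(weights > 1 + 1e-8))
    stop("correlation weights must lie in [-1, 1]")
  if (is.null(roi_labels)) {
    roi_labels <- colnames(weights)
    if (is.null(roi_labels)) roi_labels <- paste0("V", seq_len(n))
  }
  if (length(roi_labels) != n) stop("roi_labels length mismatch")
  dimnames(weights) <- list(roi_labels, roi_labels)
  structure(list(weights = weights, roi_labels = as.character(roi_labels)),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %d x %d ROIs\n", nrow(x$weights), ncol(x$weights)))
  invisible(x)
}

#' Binary network at a given sparsity
#'
#' 0/1 symmetric adjacency with zero diagonal, obtained by keeping the
#' strongest \code{round(s * N(N-1)/2)} connections by absolute weight.
#'
#' @param adjacency 0/1 symmetric matrix, zero diagonal.
#' @param sparsity scalar in (0, 1): retained fraction of possible edges.
#' @param roi_labels character labels.
#' @return An object of class \code{binary_network}.
#' @export
binary_network <- function(adjacency, sparsity = NA_real_, roi_labels = NULL) {
  adjacency <- as.matrix(adjacency)
  n <- nrow(adjacency)
  if (ncol(adjacency) != n) stop("adjacency must be square")
  storage.mode(adjacency) <- "integer"
  if (!all(adjacency %in% c(0L, 1L))) stop("adjacency must be 0/1")
  if (any(adjacency != t(adjacency))) stop("adjacency must be symmetric")
  if (any(diag(adjacency) != 0L)) stop("adjacency diagonal must be zero")
  if (is.null(roi_labels)) {
    roi_labels <- colnames(adjacency)
    if (is.null(roi_labels)) roi_labels <- paste0("V", seq_len(n))
  }
  dimnames(adjacency) <- list(roi_labels, roi_labels)
  structure(list(adjacency = adjacency, sparsity = as.numeric(sparsity),
                 roi_labels = as.character(roi_labels)),
            class = "binary_network")
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf("<binary_network> %d nodes, %d edges (sparsity %s)\n",
              nrow(x$adjacency), sum(x$adjacency) / 2,
              format(x$sparsity)))
  invisible(x)
}

#' Sparsity grid
#'
#' Uniform grid of sparsity (network cost) levels over which thresholded
#' networks are built and metric curves integrated. The default grid,
#' 0.10 to 0.34 in steps of 0.01 (25 levels), is the range in which a
#' 90-node functional network keeps mean degree above 2 ln N while both
#' groups retain small-world organisation (sigma > 1.1).
#'
#' @param s_min,s_max grid end points, 0 < s_min < s_max < 1.
#' @param delta_s positive step.
#' @return An object of class \code{sparsity_grid} with a \code{points} field.
#' @export
sparsity_grid <- function(s_min = 0.10, s_max = 0.34, delta_s = 0.01) {
  if (!(s_min > 0 && s_max < 1 && s_min < s_max)) stop("need 0 < s_min < s_max < 1")
  if (delta_s <= 0) stop("delta_s must be positive")
  k <- round((s_max - s_min) / delta_s)
  if (abs(s_min + k * delta_s - s_max) > 1e-9)
    stop("s_max must be reachable from s_min in whole delta_s steps")
  points <- s_min + delta_s * (0:k)
  structure(list(s_min = s_min, s_max = s_max, delta_s = delta_s,
                 points = points),
            class = "sparsity_grid")
}

#' @export
print.sparsity_grid <- function(x, ...) {
  cat(sprintf("<sparsity_grid> %g..%g step %g (%d levels)\n",
              x$s_min, x$s_max, x$delta_s, length(x$points)))
  invisible(x)
}
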