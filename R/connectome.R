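# Edge definition: Pearson correlation between regional mean time series,
# then binarization at a fixed network sparsity so every subject's network
# has the same number of edges.

#' Pearson correlation matrix between ROI time series
#'
#' @param ts \code{roi_timeseries} with at least 3 timepoints.
#' @return \code{connectivity_matrix} (symmetric, unit diagonal).
#' @export
correlation_matrix <- function(ts) {
  stopifnot(inherits(ts, "roi_timeseries"))
  if (nrow(ts$data) < 3L) stop("need at least 3 timepoints")
  sds <- apply(ts$data, 2, stats::sd)
  if (any(sds == 0))
    stop("constant time series for ROI(s): ",
         paste(ts$roi_labels[sds == 0], collapse = ", "))
  w <- stats::cor(ts$data)
  diag(w) <- 1
  connectivity_matrix(w, roi_labels = ts$roi_labels)
}

# round-half-up; base round() is banker's rounding
.round_half_up <- function(x) floor(x + 0.5)

#' Binarize a connectivity matrix at a target sparsity
#'
#' Keeps the \code{round(s * N(N-1)/2)} strongest connections by absolute
#' correlation (a -0.95 edge outranks a +0.9 one). Ties at the cut are broken
#' deterministically by ascending lexicographic node-pair order, so results
#' are reproducible across platforms. The diagonal is always excluded.
#'
#' @param cm \code{connectivity_matrix}.
#' @param s sparsity in (0, 1); the retained fraction of the N(N-1)/2
#'   possible edges.
#' @return \code{binary_network} with exactly the target edge count.
#' @export
binarize_at_sparsity <- function(cm, s) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  if (!(s > 0 && s < 1)) stop("sparsity must be in (0, 1)")
  n <- nrow(cm$weights)
  m_possible <- n * (n - 1) / 2
  m_keep <- .round_half_up(s * m_possible)
  if (m_keep < 1) stop("sparsity ", s, " yields zero edges for N = ", n)
  ut <- which(upper.tri(cm$weights))
  w <- abs(cm$weights[ut])
  # order: |weight| descending, then (i, j) ascending == upper.tri index order
  keep <- ut[order(-w, seq_along(ut))][seq_len(m_keep)]
  adj <- matrix(0L, n, n)
  adj[keep] <- 1L
  adj <- adj + t(adj)
  binary_network(adj, sparsity = s, roi_labels = cm$roi_labels)
}

#' Data-driven sparsity range selection
#'
#' Scans a candidate grid and applies the two standard criteria for a
#' cost range over which thresholded networks are interpretable:
#' \itemize{
#'   \item lower bound: the smallest sparsity at which the mean node degree
#'     of every subject's network is at least \code{2 log(N)} (natural log
#'     by default; the base is exposed because the literature is not
#'     uniform);
#'   \item upper bound: the largest sparsity at which every subject's network
#'     still has small-worldness \code{sigma > sigma_threshold} (default 1.1).
#' }
#'
#' @param cohort_cms list of \code{connectivity_matrix}, one per subject.
#' @param delta_s grid step (default 0.01).
#' @param sigma_threshold small-worldness bound for the upper criterion.
#' @param candidates numeric vector of candidate sparsities (default
#'   \code{seq(0.05, 0.50, delta_s)}).
#' @param log_base base of the logarithm in the degree criterion
#'   (default \code{exp(1)}).
#' @param n_null,n_swaps_per_edge null-model settings forwarded to
#'   \code{\link{small_world_params}} for the sigma criterion.
#' @param seed RNG seed for the null networks.
#' @return \code{sparsity_grid} spanning the feasible range; attribute
#'   \code{"diagnostics"} holds the per-criterion bounds.
#' @export
select_sparsity_range <- function(cohort_cms, delta_s = 0.01,
                                  sigma_threshold = 1.1,
                                  candidates = NULL,
                                  log_base = exp(1),
                                  n_null = 20L, n_swaps_per_edge = 10L,
                                  seed = NULL) {
  if (length(cohort_cms) == 0L) stop("empty cohort")
  stopifnot(all(vapply(cohort_cms, inherits, logical(1), "connectivity_matrix")))
  if (is.null(candidates)) candidates <- seq(0.05, 0.50, by = delta_s)
  candidates <- sort(candidates)
  n <- nrow(cohort_cms[[1L]]$weights)
  deg_bound <- 2 * log(n, base = log_base)

  # degree criterion: mean degree = 2 m / N with m = round(s N(N-1)/2)
  mean_deg <- 2 * .round_half_up(candidates * n * (n - 1) / 2) / n
  deg_ok <- mean_deg >= deg_bound
  if (!any(deg_ok))
    stop("degree criterion (mean degree >= ", signif(deg_bound, 4),
         ") unmet on the whole candidate grid")
  s_min <- candidates[which(deg_ok)[1L]]

  # sigma criterion, evaluated from the top of the grid downward
  if (!is.null(seed)) set.seed(seed)
  sigma_ok_at <- function(s) {
    for (cm in cohort_cms) {
      net <- binarize_at_sparsity(cm, s)
      swp <- small_world_params(net, n_null = n_null,
                                n_swaps_per_edge = n_swaps_per_edge)
      if (!(swp$sigma > sigma_threshold)) return(FALSE)
    }
    TRUE
  }
  s_max <- NA_real_
  if (sigma_threshold <= 0) {
    s_max <- candidates[length(candidates)]
  } else {
    for (s in rev(candidates[candidates > s_min])) {
      if (sigma_ok_at(s)) { s_max <- s; break }
    }
  }
  if (is.na(s_max) || s_max <= s_min)
    stop("empty feasible sparsity range: degree criterion needs s >= ", s_min,
         " but sigma > ", sigma_threshold, " fails everywhere above it")
  out <- sparsity_grid(s_min, s_max, delta_s)
  attr(out, "diagnostics") <- list(degree_bound = deg_bound,
                                   s_min_degree = s_min,
                                   s_max_sigma = s_max,
                                   sigma_threshold = sigma_threshold)
  out
}
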