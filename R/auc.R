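# Threshold-free summary: integrate each metric's curve over the sparsity
# grid with the composite trapezoidal rule, giving one scalar per subject per
# metric that does not depend on any single threshold choice.

#' Area under a metric-versus-sparsity curve
#'
#' Composite trapezoidal rule over a uniformly spaced grid:
#' \deqn{AUC = (\Delta S / 2) \sum_k [Y(S_k) + Y(S_{k+1})]}
#'
#' @param values numeric vector of metric values at consecutive grid points
#'   (at least 2).
#' @param delta_s positive grid spacing.
#' @return Scalar AUC.
#' @export
auc_over_sparsity <- function(values, delta_s) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need at least 2 grid points for an AUC")
  if (delta_s <= 0) stop("delta_s must be positive")
  if (anyNA(values)) stop("metric curve contains missing values")
  n <- length(values)
  (delta_s / 2) * sum(values[-1L] + values[-n])
}

#' Metric curves over the sparsity grid for one subject
#'
#' Binarizes the connectivity matrix at every grid point and computes the
#' global metrics (and, optionally, nodal metrics) at each sparsity.
#'
#' @param cm \code{connectivity_matrix}.
#' @param grid \code{sparsity_grid}.
#' @param n_null null networks per sparsity for gamma/lambda/sigma
#'   (default 100).
#' @param n_swaps_per_edge swaps per edge in the null model (default 10).
#' @param include_nodal also compute degree/efficiency/betweenness per node.
#' @param subject_id label carried into the output.
#' @param seed optional RNG seed.
#' @return List of class \code{metric_curves}: \code{global} (data.frame,
#'   one row per sparsity), \code{nodal} (data.frame or NULL), \code{grid},
#'   \code{subject_id}.
#' @export
metric_curves <- function(cm, grid = sparsity_grid(), n_null = 100L,
                          n_swaps_per_edge = 10L, include_nodal = TRUE,
                          subject_id = "subject", seed = NULL) {
  stopifnot(inherits(cm, "connectivity_matrix"),
            inherits(grid, "sparsity_grid"))
  if (!is.null(seed)) set.seed(seed)
  glob <- vector("list", length(grid$points))
  nod <- if (include_nodal) vector("list", length(grid$points)) else NULL
  for (i in seq_along(grid$points)) {
    net <- binarize_at_sparsity(cm, grid$points[i])
    glob[[i]] <- global_metrics(net, n_null = n_null,
                                n_swaps_per_edge = n_swaps_per_edge)
    if (include_nodal) {
      nm <- nodal_metrics(net)
      nm$sparsity <- grid$points[i]
      nod[[i]] <- nm
    }
  }
  structure(list(global = do.call(rbind, glob),
                 nodal = if (include_nodal) do.call(rbind, nod) else NULL,
                 grid = grid, subject_id = subject_id),
            class = "metric_curves")
}

#' @export
print.metric_curves <- function(x, ...) {
  cat("<metric_curves> subject:", x$subject_id, "|",
      nrow(x$global), "sparsity levels",
      if (!is.null(x$nodal)) "| nodal metrics included", "\n")
  invisible(x)
}

#' AUC of every metric curve
#'
#' Integrates each global metric (and each nodal metric per node, when
#' present) over the sparsity grid.
#'
#' @param curves \code{metric_curves}.
#' @return Long data.frame with columns \code{subject_id}, \code{metric},
#'   \code{node} (NA for global metrics), \code{auc}.
#' @export
auc_table <- function(curves) {
  stopifnot(inherits(curves, "metric_curves"))
  ds <- curves$grid$delta_s
  gm <- setdiff(names(curves$global), "sparsity")
  out <- data.frame(subject_id = curves$subject_id, metric = gm, node = NA_character_,
                    auc = vapply(gm, function(m)
                      auc_over_sparsity(curves$global[[m]], ds), numeric(1)),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(curves$nodal)) {
    nodes <- unique(curves$nodal$node)
    for (m in c("degree", "efficiency", "betweenness")) {
      vals <- vapply(nodes, function(nd)
        auc_over_sparsity(curves$nodal[[m]][curves$nodal$node == nd], ds),
        numeric(1))
      out <- rbind(out, data.frame(subject_id = curves$subject_id,
                                   metric = paste0("nodal_", m), node = nodes,
                                   auc = vals, row.names = NULL,
                                   stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}
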