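# Topological metrics of binary undirected networks. All-pairs distances and
# betweenness run in compiled code (BFS / Brandes accumulation); clustering
# uses the adjacency triple product. Conventions where the graph literature
# splits: nodes of degree < 2 contribute clustering 0; local efficiency of a
# node with < 2 neighbours is 0; characteristic path length on a fragmented
# graph averages over reachable pairs only and flags the event.

.adjm <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  net$adjacency
}

#' Node degrees
#' @param net \code{binary_network}.
#' @return Integer vector of length N.
#' @export
degree_vector <- function(net) as.integer(rowSums(.adjm(net)))

#' Clustering coefficient
#'
#' Per-node C_i = 2 t_i / (k_i (k_i - 1)) where t_i is the number of
#' triangles through node i; nodes with degree < 2 get C_i = 0. The global
#' value Cp is the mean over all nodes.
#'
#' @param net \code{binary_network} with at least 3 nodes.
#' @return List with \code{cp} (scalar mean) and \code{per_node} (vector).
#' @export
clustering_coefficient <- function(net) {
  A <- .adjm(net)
  if (nrow(A) < 3L) stop("need at least 3 nodes")
  A <- matrix(as.numeric(A), nrow(A))
  k <- rowSums(A)
  tri2 <- diag(A %*% A %*% A)  # = 2 * triangles per node
  per_node <- ifelse(k < 2, 0, tri2 / (k * (k - 1)))
  list(cp = mean(per_node), per_node = per_node)
}

#' All-pairs shortest-path length matrix
#'
#' @param net \code{binary_network}.
#' @return N x N numeric matrix; \code{Inf} for unreachable pairs, 0 diagonal.
#' @export
distance_matrix <- function(net) {
  D <- bfs_distances_cpp(.adjm(net))
  D[D < 0L] <- NA_integer_
  D <- matrix(as.numeric(D), nrow(D))
  D[is.na(D)] <- Inf
  dimnames(D) <- dimnames(net$adjacency)
  D
}

#' Characteristic path length
#'
#' Mean shortest-path length over all reachable ordered pairs. If the network
#' is fragmented, unreachable pairs are excluded and the attribute
#' \code{"disconnected"} is set to \code{TRUE}.
#'
#' @param net \code{binary_network} with at least 2 nodes and 1 edge.
#' @return Scalar Lp with logical attribute \code{"disconnected"}.
#' @export
characteristic_path_length <- function(net) {
  A <- .adjm(net)
  if (nrow(A) < 2L) stop("need at least 2 nodes")
  if (sum(A) == 0L) stop("network has no edges; path length undefined")
  D <- distance_matrix(net)
  off <- D[row(D) != col(D)]
  finite <- is.finite(off)
  lp <- mean(off[finite])
  attr(lp, "disconnected") <- !all(finite)
  lp
}

#' Global efficiency
#'
#' E_glob = mean over ordered pairs i != j of 1/d_ij, with unreachable pairs
#' contributing 0; lies in [0, 1].
#'
#' @param net \code{binary_network} with at least 2 nodes.
#' @return Scalar.
#' @export
global_efficiency <- function(net) {
  A <- .adjm(net)
  n <- nrow(A)
  if (n < 2L) stop("need at least 2 nodes")
  D <- distance_matrix(net)
  inv <- 1 / D
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Local efficiency
#'
#' Mean over nodes of the global efficiency of the subgraph induced by each
#' node's neighbours; nodes with < 2 neighbours contribute 0.
#'
#' @param net \code{binary_network} with at least 2 nodes.
#' @return Scalar in [0, 1].
#' @export
local_efficiency <- function(net) {
  A <- .adjm(net)
  n <- nrow(A)
  if (n < 2L) stop("need at least 2 nodes")
  vals <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] != 0L)
    if (length(nb) < 2L) return(0)
    global_efficiency(binary_network(A[nb, nb, drop = FALSE]))
  }, numeric(1))
  mean(vals)
}

#' Nodal centrality metrics
#'
#' Degree, nodal efficiency E_i = mean_j (1/d_ij) over the other N-1 nodes
#' (unreachable pairs contribute 0), and betweenness centrality in the
#' unnormalized pair-count convention (each unordered pair {s, t} distributes
#' one unit over the interior vertices of its shortest paths, weighted by
#' shortest-path multiplicity).
#'
#' @param net \code{binary_network} with at least 2 nodes.
#' @param normalize_betweenness divide betweenness by (N-1)(N-2)/2
#'   (default \code{FALSE}).
#' @return \code{data.frame} with columns \code{node}, \code{degree},
#'   \code{efficiency}, \code{betweenness}.
#' @export
nodal_metrics <- function(net, normalize_betweenness = FALSE) {
  A <- .adjm(net)
  n <- nrow(A)
  if (n < 2L) stop("need at least 2 nodes")
  D <- distance_matrix(net)
  inv <- 1 / D
  diag(inv) <- 0
  eff <- rowSums(inv) / (n - 1)
  bc <- betweenness_cpp(A)
  if (normalize_betweenness) bc <- bc / ((n - 1) * (n - 2) / 2)
  data.frame(node = net$roi_labels, degree = as.integer(rowSums(A)),
             efficiency = eff, betweenness = bc,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Degree-preserving random reference network
#'
#' Maslov-Sneppen double-edge swaps: repeatedly picks two edges (a-b, c-d)
#' and rewires them to (a-d, c-b) when this creates no self-loop or
#' multi-edge. The degree sequence is preserved exactly; connectivity is not
#' enforced. Rigid graphs that admit no legal swap (e.g. complete graphs)
#' are returned unchanged with a warning.
#'
#' @param net \code{binary_network} with at least 2 edges.
#' @param n_swaps_per_edge target number of successful swaps per edge
#'   (default 10); the attempt budget is 20x the target.
#' @param seed optional RNG seed (\code{set.seed} otherwise governs).
#' @return Rewired \code{binary_network}.
#' @export
random_reference <- function(net, n_swaps_per_edge = 10L, seed = NULL) {
  A <- .adjm(net)
  m <- sum(A) / 2
  if (m < 2) stop("need at least 2 edges to rewire")
  if (!is.null(seed)) set.seed(seed)
  target <- as.integer(ceiling(n_swaps_per_edge * m))
  B <- rewire_ms_cpp(A, target)
  if (attr(B, "swaps") == 0L)
    warning("no legal degree-preserving swap found; returning input network")
  attr(B, "swaps") <- NULL
  binary_network(B, sparsity = net$sparsity, roi_labels = net$roi_labels)
}

#' Normalized small-world parameters
#'
#' gamma = Cp / mean(Cp of null networks), lambda = Lp / mean(Lp of nulls),
#' sigma = gamma / lambda, with nulls drawn by degree-preserving rewiring.
#' A null that happens to have zero clustering is resampled once and, if
#' still degenerate, excluded with a warning.
#'
#' @param net \code{binary_network}.
#' @param n_null number of null networks (default 100).
#' @param n_swaps_per_edge swaps per edge per null (default 10).
#' @param seed optional RNG seed.
#' @return List with \code{gamma}, \code{lambda}, \code{sigma}, \code{cp},
#'   \code{lp}, and the null means.
#' @export
small_world_params <- function(net, n_null = 100L, n_swaps_per_edge = 10L,
                               seed = NULL) {
  if (n_null < 1L) stop("n_null must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  cp <- clustering_coefficient(net)$cp
  lp <- as.numeric(characteristic_path_length(net))
  cps <- numeric(0); lps <- numeric(0)
  for (i in seq_len(n_null)) {
    null <- suppressWarnings(random_reference(net, n_swaps_per_edge))
    c0 <- clustering_coefficient(null)$cp
    if (c0 == 0) {  # resample once, then drop
      null <- suppressWarnings(random_reference(net, n_swaps_per_edge))
      c0 <- clustering_coefficient(null)$cp
      if (c0 == 0) {
        warning("null network with zero clustering excluded")
        next
      }
    }
    cps <- c(cps, c0)
    lps <- c(lps, as.numeric(characteristic_path_length(null)))
  }
  if (length(cps) == 0L) stop("all null networks degenerate (zero clustering)")
  gamma <- cp / mean(cps)
  lambda <- lp / mean(lps)
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda,
       cp = cp, lp = lp, cp_null = mean(cps), lp_null = mean(lps),
       n_null_used = length(cps))
}

#' All global metrics of one binary network
#'
#' @param net \code{binary_network}.
#' @param n_null,n_swaps_per_edge null-model settings for gamma/lambda/sigma.
#' @param seed optional RNG seed.
#' @return One-row \code{data.frame}: sparsity, cp, lp, gamma, lambda, sigma,
#'   e_glob, e_loc.
#' @export
global_metrics <- function(net, n_null = 100L, n_swaps_per_edge = 10L,
                           seed = NULL) {
  sw <- small_world_params(net, n_null = n_null,
                           n_swaps_per_edge = n_swaps_per_edge, seed = seed)
  data.frame(sparsity = net$sparsity, cp = sw$cp, lp = sw$lp,
             gamma = sw$gamma, lambda = sw$lambda, sigma = sw$sigma,
             e_glob = global_efficiency(net), e_loc = local_efficiency(net))
}
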