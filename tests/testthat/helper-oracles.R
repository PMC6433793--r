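# Independent brute-force oracles used to cross-check the package's graph
# metrics. They deliberately avoid the implementation's algorithms: distances
# come from Floyd-Warshall (not BFS), betweenness from explicit
# shortest-path counting over the distance matrix (not Brandes
# accumulation), clustering from direct triangle enumeration.

oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A == 1] <- 1
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], `+`))
  D
}

oracle_lp <- function(A) {
  D <- oracle_distances(A)
  off <- D[row(D) != col(D)]
  mean(off[is.finite(off)])
}

oracle_eglob <- function(A) {
  n <- nrow(A)
  D <- oracle_distances(A)
  inv <- 1 / D
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

oracle_eloc <- function(A) {
  n <- nrow(A)
  mean(vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] == 1)
    if (length(nb) < 2) return(0)
    oracle_eglob(A[nb, nb, drop = FALSE])
  }, numeric(1)))
}

oracle_nodal_eff <- function(A) {
  n <- nrow(A)
  D <- oracle_distances(A)
  inv <- 1 / D
  diag(inv) <- 0
  rowSums(inv) / (n - 1)
}

oracle_clustering <- function(A) {
  n <- nrow(A)
  per <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    tri <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k)
      tri <- tri + A[nb[a], nb[b]]
    2 * tri / (k * (k - 1))
  }, numeric(1))
  list(cp = mean(per), per_node = per)
}

# shortest-path counts sigma[s, v] by dynamic programming over distance
# shells, then pair-count betweenness
oracle_betweenness <- function(A) {
  n <- nrow(A)
  D <- oracle_distances(A)
  S <- matrix(0, n, n)
  for (s in seq_len(n)) {
    S[s, s] <- 1
    ds <- D[s, ]
    dmax <- suppressWarnings(max(ds[is.finite(ds)]))
    if (!is.finite(dmax) || dmax < 1) next
    for (d in seq_len(dmax)) {
      for (v in which(ds == d)) {
        prev <- which(A[, v] == 1 & ds == d - 1)
        S[s, v] <- sum(S[s, prev])
      }
    }
  }
  bc <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(D[s, t]) || D[s, t] < 2) next
    for (v in setdiff(seq_len(n), c(s, t))) {
      if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
          D[s, v] + D[v, t] == D[s, t]) {
        bc[v] <- bc[v] + S[s, v] * S[v, t] / S[s, t]
      }
    }
  }
  bc
}

# brute-force BH step-up: largest k with p_(k) <= k q / m, reject those
oracle_bh_reject <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ks <- which(p[o] <= seq_len(m) * q / m)
  reject <- logical(m)
  if (length(ks) > 0) reject[o[seq_len(max(ks))]] <- TRUE
  reject
}

# fixture graphs
ring_lattice <- function(n, k) {
  A <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(k %/% 2)) {
    t <- ((i - 1 + j) %% n) + 1
    A[i, t] <- 1L; A[t, i] <- 1L
  }
  A
}

star_graph <- function(n) {
  A <- matrix(0L, n, n)
  A[1, 2:n] <- 1L; A[2:n, 1] <- 1L
  A
}

random_adjacency <- function(n, p_edge = 0.4) {
  A <- matrix(0L, n, n)
  ut <- upper.tri(A)
  A[ut] <- as.integer(stats::runif(sum(ut)) < p_edge)
  A + t(A)
}

as_net <- function(A) binary_network(A)
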