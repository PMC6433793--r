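# Global and nodal topology metrics against closed forms and brute-force
# oracles, plus the degree-preserving null model.

test_that("closed-form fixtures: K3, paths, stars, cycles, lattices", {
  # triangle
  expect_equal(clustering_coefficient(as_net(ring_lattice(3, 2)))$cp, 1)
  # path on 4 nodes has no triangles
  P4 <- matrix(0L, 4, 4); P4[cbind(1:3, 2:4)] <- 1L; P4 <- P4 + t(P4)
  expect_equal(clustering_coefficient(as_net(P4))$cp, 0)
  # complete graph K10: Lp = 1, Eglob = 1, Eloc = 1, betweenness all 0
  K10 <- matrix(1L, 10, 10); diag(K10) <- 0L
  expect_equal(as.numeric(characteristic_path_length(as_net(K10))), 1)
  expect_equal(global_efficiency(as_net(K10)), 1)
  expect_equal(local_efficiency(as_net(K10)), 1)
  K4 <- matrix(1L, 4, 4); diag(K4) <- 0L
  expect_equal(nodal_metrics(as_net(K4))$betweenness, rep(0, 4))

  # star n = 10
  S10 <- as_net(star_graph(10))
  expect_equal(as.numeric(characteristic_path_length(S10)), 1.8)
  expect_equal(global_efficiency(S10), 0.6)
  expect_equal(local_efficiency(S10), 0)  # centre's neighbours edgeless
  nm <- nodal_metrics(S10)
  expect_equal(nm$degree, c(9L, rep(1L, 9)))
  expect_equal(nm$efficiency[1], 1)
  expect_equal(nm$efficiency[-1], rep(5 / 9, 9))
  expect_equal(nm$betweenness, c(36, rep(0, 9)))

  # cycle n = 5: vertex-transitive
  C5 <- nodal_metrics(as_net(ring_lattice(5, 2)))
  expect_true(all(C5$degree == 2L))
  expect_equal(length(unique(round(C5$betweenness, 12))), 1L)

  # ring lattice n = 20, k = 4: Cp = 0.5
  expect_equal(clustering_coefficient(as_net(ring_lattice(20, 4)))$cp, 0.5)
})

test_that("all metrics agree exactly with brute-force oracles on random graphs", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(4:12, 1)
    A <- random_adjacency(n, runif(1, 0.2, 0.7))
    if (sum(A) == 0) next
    net <- as_net(A)
    expect_equal(clustering_coefficient(net)$per_node,
                 oracle_clustering(A)$per_node, tolerance = 1e-12)
    expect_equal(as.numeric(characteristic_path_length(net)), oracle_lp(A),
                 tolerance = 1e-12)
    expect_equal(global_efficiency(net), oracle_eglob(A), tolerance = 1e-12)
    expect_equal(local_efficiency(net), oracle_eloc(A), tolerance = 1e-12)
    nm <- nodal_metrics(net)
    expect_equal(nm$degree, as.integer(rowSums(A)))
    expect_equal(nm$efficiency, oracle_nodal_eff(A), tolerance = 1e-12)
    expect_equal(nm$betweenness, oracle_betweenness(A), tolerance = 1e-9)
  }
})

test_that("metrics match igraph on larger graphs", {
  skip_if_not_installed("igraph")
  set.seed(5)
  for (i in 1:5) {
    A <- random_adjacency(40, 0.15)
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    net <- as_net(A)
    expect_equal(mean(igraph::transitivity(g, type = "localundirected",
                                           isolates = "zero")),
                 clustering_coefficient(net)$cp, tolerance = 1e-12)
    expect_equal(igraph::global_efficiency(g), global_efficiency(net),
                 tolerance = 1e-12)
    expect_equal(unname(igraph::betweenness(g)),
                 nodal_metrics(net)$betweenness, tolerance = 1e-9)
    expect_equal(igraph::mean_distance(g, unconnected = TRUE),
                 as.numeric(characteristic_path_length(net)),
                 tolerance = 1e-12)
  }
})

test_that("metrics are invariant under node relabeling", {
  set.seed(17)
  A <- random_adjacency(15, 0.3)
  perm <- sample(15)
  Ap <- A[perm, perm]
  expect_equal(clustering_coefficient(as_net(Ap))$cp,
               clustering_coefficient(as_net(A))$cp, tolerance = 1e-12)
  expect_equal(global_efficiency(as_net(Ap)), global_efficiency(as_net(A)),
               tolerance = 1e-12)
  expect_equal(sort(nodal_metrics(as_net(Ap))$betweenness),
               sort(nodal_metrics(as_net(A))$betweenness), tolerance = 1e-9)
})

test_that("global efficiency is monotone under edge addition", {
  set.seed(31)
  w <- cov2cor(crossprod(matrix(rnorm(800), 40, 20)))
  cm <- connectivity_matrix(w)
  effs <- vapply(seq(0.1, 0.5, 0.05), function(s)
    global_efficiency(binarize_at_sparsity(cm, s)), numeric(1))
  expect_true(all(diff(effs) >= -1e-12))
})

test_that("disconnected graphs: reachable-pair convention with flag", {
  two_k3 <- matrix(0L, 6, 6)
  two_k3[1:3, 1:3] <- 1L; two_k3[4:6, 4:6] <- 1L; diag(two_k3) <- 0L
  lp <- characteristic_path_length(as_net(two_k3))
  expect_equal(as.numeric(lp), 1)
  expect_true(attr(lp, "disconnected"))
  # empty graph: Lp errors, Eglob = 0
  empty <- matrix(0L, 5, 5)
  expect_error(characteristic_path_length(as_net(empty)), "no edges")
  expect_equal(global_efficiency(as_net(empty)), 0)
})

test_that("random_reference preserves degrees and destroys lattice clustering", {
  set.seed(8)
  A <- random_adjacency(20, 0.3)
  net <- as_net(A)
  null <- random_reference(net, n_swaps_per_edge = 10, seed = 1)
  expect_equal(unname(rowSums(null$adjacency)), rowSums(A))
  expect_true(all(diag(null$adjacency) == 0L))
  expect_identical(null$adjacency, t(null$adjacency))
  # determinism under seed
  null2 <- random_reference(net, n_swaps_per_edge = 10, seed = 1)
  expect_identical(null$adjacency, null2$adjacency)

  # rigid complete graph returned unchanged with a warning
  K5 <- matrix(1L, 5, 5); diag(K5) <- 0L
  expect_warning(nk5 <- random_reference(as_net(K5), 10, seed = 2), "no legal")
  expect_equal(nk5$adjacency, K5, ignore_attr = TRUE)

  # rewiring a ring lattice destroys its clustering nearly always
  lat <- as_net(ring_lattice(100, 6))
  cp0 <- clustering_coefficient(lat)$cp
  expect_equal(cp0, 0.6)
  drops <- vapply(1:100, function(s)
    clustering_coefficient(random_reference(lat, 10, seed = s))$cp < cp0,
    logical(1))
  expect_gte(sum(drops), 95)
})

test_that("small-world parameters behave in the canonical regimes", {
  set.seed(12)
  # an Erdos-Renyi graph is its own null up to noise: gamma, lambda ~ 1
  A <- random_adjacency(100, 0.1)
  sw <- small_world_params(as_net(A), n_null = 50, seed = 4)
  expect_gt(sw$gamma, 0.8); expect_lt(sw$gamma, 1.2)
  expect_gt(sw$lambda, 0.9); expect_lt(sw$lambda, 1.1)
  expect_equal(sw$sigma, sw$gamma / sw$lambda, tolerance = 1e-12)

  # Watts-Strogatz small-world regime: gamma >> 1, lambda modest
  hits <- 0L
  for (s in 1:20) {
    g <- make_small_world_graph(90, 8, 0.1, seed = s)
    sw <- small_world_params(as_net(g$adjacency), n_null = 10, seed = s + 1000)
    if (sw$gamma > 1.5 && sw$lambda < 1.5) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})
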