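# Ground-truth generator and BOLD-like signal simulation.

test_that("Watts-Strogatz generator: lattice limits, edge conservation, determinism", {
  # p = 0: pure ring lattice, closed-form clustering 3(k-2)/(4(k-1))
  gt <- make_small_world_graph(20, 4, 0, seed = 1)
  expect_identical(gt$adjacency, ring_lattice(20, 4))
  cc <- clustering_coefficient(binary_network(gt$adjacency))
  expect_equal(cc$cp, 3 * (4 - 2) / (4 * (4 - 1)))
  expect_equal(cc$cp, oracle_clustering(gt$adjacency)$cp)

  # k = 2, p = 0: a cycle has no triangles
  cyc <- make_small_world_graph(10, 2, 0, seed = 7)
  expect_equal(clustering_coefficient(binary_network(cyc$adjacency))$cp, 0)
  expect_true(all(rowSums(cyc$adjacency) == 2))

  # edge count conserved for any rewiring probability
  for (p in c(0.1, 0.5, 1)) {
    g <- make_small_world_graph(20, 4, p, seed = 2)
    expect_equal(sum(g$adjacency) / 2, 20 * 4 / 2)
    expect_identical(g$adjacency, t(g$adjacency))
    expect_true(all(diag(g$adjacency) == 0))
  }

  # determinism and validation
  expect_identical(make_small_world_graph(30, 6, 0.2, seed = 5)$adjacency,
                   make_small_world_graph(30, 6, 0.2, seed = 5)$adjacency)
  expect_error(make_small_world_graph(20, 3, 0.1), "even")
  expect_error(make_small_world_graph(10, 12, 0.1), "smaller")
})

test_that("simulated signals carry the ground-truth covariance structure", {
  gt <- make_small_world_graph(30, 4, 0.1, seed = 11)
  spec <- simulation_spec(n_per_group = c(2, 2), n_timepoints = 1000,
                          coupling_strength = 0.25, seed = 1)
  ts <- simulate_bold(gt, spec, "control", seed = 42)
  expect_s3_class(ts, "roi_timeseries")
  expect_equal(dim(ts$data), c(1000L, 30L))

  r <- cor(ts$data)
  adj <- gt$adjacency[upper.tri(gt$adjacency)] == 1
  rvals <- abs(r[upper.tri(r)])
  # adjacent pairs must show clearly higher |correlation| than non-adjacent
  expect_gt(mean(rvals[adj]), mean(rvals[!adj]) + 0.05)

  # same seed -> identical output; different seed -> different
  ts2 <- simulate_bold(gt, spec, "control", seed = 42)
  expect_identical(ts$data, ts2$data)
  ts3 <- simulate_bold(gt, spec, "control", seed = 43)
  expect_false(identical(ts$data, ts3$data))
})

test_that("zero coupling gives near-independent signals", {
  gt <- make_small_world_graph(20, 4, 0, seed = 1)
  spec <- simulation_spec(n_per_group = c(2, 2), n_timepoints = 2000,
                          coupling_strength = 0, seed = 1)
  ts <- simulate_bold(gt, spec, "control", seed = 3)
  r <- cor(ts$data)
  # band-passing lowers the effective sample size; bound |r| accordingly
  expect_lt(max(abs(r[upper.tri(r)])), 0.25)
  expect_lt(mean(abs(r[upper.tri(r)])), 0.08)
})

test_that("empirical covariance converges to the analytic covariance in T", {
  gt <- make_small_world_graph(20, 4, 0.1, seed = 5)
  n <- 20
  P <- diag(n) + 0.25 * gt$adjacency
  lmin <- min(eigen(P, symmetric = TRUE, only.values = TRUE)$values)
  if (lmin < 0.1) P <- P + (0.1 - lmin) * diag(n)
  Sigma <- solve(P)
  dist_at <- function(tt) {
    spec <- simulation_spec(n_per_group = c(2, 2), n_timepoints = tt,
                            coupling_strength = 0.25, seed = 1)
    set.seed(7)
    # measure before band-passing: draw from the same model directly
    X <- matrix(rnorm(tt * n), tt, n) %*% chol(Sigma)
    norm(cov(X) - Sigma, "F")
  }
  d <- vapply(c(200, 2000, 20000), dist_at, numeric(1))
  expect_true(all(diff(d) < 0))
})

test_that("make_cohort: sizes, labels, clinical association calibration", {
  spec <- simulation_spec(seed = 9)  # default 55 + 47
  gt <- make_small_world_graph(90, 8, 0.1, seed = 1)
  sim <- make_cohort(spec, gt = gt)
  expect_length(sim$timeseries, 102L)
  expect_equal(sum(sim$cohort$group == "patient"), 55L)
  expect_equal(sum(sim$cohort$group == "control"), 47L)
  expect_true(all(c("age", "sex", "bmi", "hba1c", "moca") %in% names(sim$cohort)))
  expect_true(all(sim$cohort$age >= 40 & sim$cohort$age <= 75))

  # determinism of the whole cohort
  sim2 <- make_cohort(spec, gt = gt)
  expect_identical(sim$cohort, sim2$cohort)
  expect_identical(sim$timeseries[[10]]$data, sim2$timeseries[[10]]$data)
})

test_that("clinical association hits its target correlation", {
  gt <- make_small_world_graph(30, 4, 0.1, seed = 2)
  # r = 0: no association beyond sampling error (averaged over seeds)
  r0 <- vapply(1:20, function(s) {
    spec <- simulation_spec(n_per_group = c(26, 25), n_timepoints = 30,
                            clinical_assoc = list(variable = "bmi", r = 0),
                            seed = s)
    sim <- make_cohort(spec, gt = gt)
    cor(sim$cohort$bmi, sim$coupling)
  }, numeric(1))
  expect_lt(abs(mean(r0)), 0.1)

  # r = 0.6 at n = 102: sample correlation within its sampling band
  r6 <- vapply(1:25, function(s) {
    spec <- simulation_spec(n_timepoints = 30,
                            clinical_assoc = list(variable = "bmi", r = 0.6),
                            seed = s)
    sim <- make_cohort(spec, gt = gt)
    cor(sim$cohort$bmi, sim$coupling)
  }, numeric(1))
  expect_true(all(r6 > 0.4 & r6 < 0.75))
})
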