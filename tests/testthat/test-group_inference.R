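# Residualization, permutation tests, BH-FDR, partial correlations,
# demographics.

test_that("residualize is the OLS projection", {
  set.seed(3)
  n <- 60
  age <- rnorm(n, 50, 8)
  y <- rnorm(n)
  # orthogonal covariate: residual = demeaned values
  q <- qr.Q(qr(cbind(y - mean(y), rnorm(n))))
  ortho <- q[, 2]
  expect_equal(residualize(y, ortho), y - mean(y) -
                 ortho * 0, tolerance = 1e-8)
  # exactly linear signal vanishes
  lin <- 3 + 2 * age
  expect_lt(max(abs(residualize(lin, age))), 1e-8 * max(abs(lin)))
  # recovery: adding beta*age then residualizing restores the demeaned signal
  base <- residualize(y, age)
  spiked <- base + 0.8 * age
  expect_equal(residualize(spiked, age), base, tolerance = 1e-8)
  # collinear covariates warn
  expect_warning(residualize(y, cbind(age, age)), "collinear")
})

test_that("permutation test: determinism, constants, exhaustive enumeration", {
  set.seed(7)
  vals <- rnorm(20)
  grp <- rep(c("control", "patient"), each = 10)
  r1 <- permutation_test(vals, grp, n_perm = 500, seed = 11)
  r2 <- permutation_test(vals, grp, n_perm = 500, seed = 11)
  expect_identical(r1$p_value, r2$p_value)
  expect_equal(r1$observed_diff,
               mean(vals[grp == "patient"]) - mean(vals[grp == "control"]))
  expect_equal(r1$p_value,
               (sum(abs(r1$null_diffs) >= abs(r1$observed_diff)) + 1) / 501)

  # constant values -> p = 1
  rc <- permutation_test(rep(2, 12), rep(c("a", "b"), 6), n_perm = 199, seed = 1)
  expect_equal(rc$p_value, 1)

  # exhaustive: {10,10,10} vs {0,0,0}: 2 of the 20 splits reach |10|
  re <- permutation_test(c(10, 10, 10, 0, 0, 0),
                         rep(c("A", "B"), each = 3), exhaustive = TRUE)
  expect_equal(re$p_value, 2 / 20)

  # exhaustive equals enumeration oracle on random small cohorts
  for (i in 1:10) {
    nn <- sample(6:10, 1); n2 <- sample(3:(nn - 3), 1)
    v <- rnorm(nn)
    g <- c(rep("a", nn - n2), rep("b", n2))
    res <- permutation_test(v, g, exhaustive = TRUE)
    combs <- combn(nn, n2)
    diffs <- apply(combs, 2, function(idx)
      mean(v[idx]) - mean(v[-idx]))
    obs <- mean(v[g == "b"]) - mean(v[g == "a"])
    expect_equal(res$p_value, mean(abs(diffs) >= abs(obs) - 1e-12))
  }
})

test_that("fdr_bh matches the brute-force step-up oracle", {
  # worked example: all four pass at q = 0.05
  out <- fdr_bh(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_true(all(out$reject))
  expect_equal(out$p_adjusted, c(0.04, 0.04, 0.04, 0.04))
  # degenerate cases
  expect_false(any(fdr_bh(rep(1, 5), 0.05)$reject))
  expect_equal(fdr_bh(0.03, 0.05)$p_adjusted, 0.03)

  set.seed(13)
  for (i in 1:1000) {
    m <- sample(1:40, 1)
    p <- runif(m)^sample(1:3, 1)
    q <- runif(1, 0.01, 0.2)
    out <- fdr_bh(p, q)
    expect_identical(out$reject, oracle_bh_reject(p, q))
    # adjusted p agrees with stats::p.adjust reference
    expect_equal(out$p_adjusted, p.adjust(p, "BH"), tolerance = 1e-12)
  }
})

test_that("partial correlation: reductions and closed form", {
  set.seed(23)
  n <- 50
  x <- rnorm(n); y <- 0.5 * x + rnorm(n); z <- rnorm(n)
  # no covariates -> plain Pearson (same r and p as cor.test)
  pc <- partial_correlation(x, y)
  ct <- cor.test(x, y)
  expect_equal(pc$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(pc$p, ct$p.value, tolerance = 1e-12)
  # y = x -> r = 1 with any covariates
  expect_equal(partial_correlation(x, x, cbind(z))$r, 1, tolerance = 1e-12)
  # textbook closed form for one covariate
  x2 <- rnorm(n) + z; y2 <- rnorm(n) + 0.7 * z
  rxy <- cor(x2, y2); rxz <- cor(x2, z); ryz <- cor(y2, z)
  closed <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  expect_equal(partial_correlation(x2, y2, cbind(z))$r, closed,
               tolerance = 1e-10)
  # zero-variance residual errors
  expect_error(partial_correlation(z, rep(1, n) + 0 * z, NULL), "zero-variance")
})

test_that("permutation type-I error is calibrated at the nominal level", {
  # 1000 independent null cohorts of 15 + 15, shared permutation stream
  set.seed(101)
  nsim <- 1000
  V <- matrix(rnorm(30 * nsim), 30, nsim)
  grp <- rep(c("a", "b"), each = 15)
  res <- permutation_test(V, grp, n_perm = 999, seed = 55)
  rate <- mean(res$p_value <= 0.05)
  expect_gte(rate, 0.035)
  expect_lte(rate, 0.065)
})

test_that("demographics comparison reproduces the exact-test convention", {
  # cohort carrying the printed gender margin 35/20 vs 21/26
  cohort <- data.frame(
    subject_id = sprintf("s%03d", 1:102),
    group = c(rep("patient", 55), rep("control", 47)),
    sex = c(rep(1, 35), rep(0, 20), rep(1, 21), rep(0, 26)),
    age = c(rnorm(55, 53.3, 9), rnorm(47, 53.3, 7.7)))
  tab <- demographics_compare(cohort)
  p_sex <- tab$p[tab$variable == "sex"]
  expect_equal(p_sex,
               fisher.test(matrix(c(35, 21, 20, 26), 2))$p.value,
               tolerance = 1e-12)
  # the uncorrected chi-squared variant is exposed and differs
  tab2 <- demographics_compare(cohort, chisq_variant = "pearson")
  expect_lt(tab2$p[tab2$variable == "sex"], p_sex)
  # balanced table -> p = 1
  bal <- data.frame(subject_id = sprintf("s%d", 1:20),
                    group = rep(c("a", "b"), each = 10),
                    sex = rep(c(0, 1), 10),
                    age = rnorm(20))
  tb <- demographics_compare(bal)
  expect_equal(tb$p[tb$variable == "sex"], 1)
  # identical continuous values -> t = 0, p = 1
  same <- data.frame(subject_id = sprintf("s%d", 1:10),
                     group = rep(c("a", "b"), each = 5),
                     bmi = rep(c(20, 21, 22, 23, 24), 2))
  ts <- demographics_compare(same, continuous = "bmi", categorical = character(0))
  expect_equal(ts$p[ts$variable == "bmi"], 1)
})

test_that("compare_groups wires residualization, permutation and FDR together", {
  set.seed(41)
  n <- 30
  cohort <- data.frame(subject_id = sprintf("s%02d", 1:n),
                       group = rep(c("control", "patient"), each = 15),
                       age = rnorm(n, 50, 8), sex = rbinom(n, 1, 0.5))
  # 5 nodes; node n3 carries a real group effect, all confounded with age
  effect <- ifelse(cohort$group == "patient", 2, 0)
  aucs <- do.call(rbind, lapply(1:5, function(k) {
    data.frame(subject_id = cohort$subject_id, metric = "nodal_efficiency",
               node = paste0("n", k),
               auc = rnorm(n, sd = 0.3) + 0.05 * cohort$age +
                 if (k == 3) effect else 0)
  }))
  res <- compare_groups(aucs, cohort, n_perm = 999, seed = 3)
  expect_equal(nrow(res), 5L)
  expect_true(res$significant[res$node == "n3"])
  expect_equal(sum(res$significant), 1L)
  expect_true(all(res$p_fdr >= res$p))
})
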