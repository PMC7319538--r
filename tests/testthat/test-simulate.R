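test_that("expected_degree 0 gives an empty graph with zero blocks", {
  cfg <- simulation_config(3, 2, 3, expected_degree = 0, n = 10, seed = 1)
  m <- random_mixed_graph(cfg)
  expect_equal(nrow(m$graph$edges), 0L)
  expect_true(all(m$params$beta == 0))
  expect_true(all(m$params$rho == 0))
  expect_true(all(m$params$phi == 0))
  expect_error(random_mixed_graph(
    simulation_config(3, 2, expected_degree = 5, n = 10)), "expected_degree")
})

test_that("realized degree matches the Erdos-Renyi expectation", {
  degs <- vapply(1:50, function(sd) {
    cfg <- simulation_config(5, 5, 3, expected_degree = 2, n = 10, seed = sd)
    m <- random_mixed_graph(cfg)
    2 * nrow(m$graph$edges) / 10
  }, numeric(1))
  p <- 10; q <- 2 / (p - 1)
  npairs <- p * (p - 1) / 2
  se <- sqrt(npairs * q * (1 - q)) * 2 / p / sqrt(50)
  expect_lt(abs(mean(degs) - 2), 3 * se)
})

test_that("generator parameter blocks respect the centering conventions", {
  cfg <- simulation_config(5, 5, 3, expected_degree = 3, n = 10, seed = 7)
  m <- random_mixed_graph(cfg)
  pr <- m$params
  for (s in 1:5) for (j in 1:5) {
    v <- pr$rho[pr$rows[[j]], s]
    expect_lt(abs(sum(v)), 1e-12)
  }
  for (r in 1:4) for (j in (r + 1):5) {
    M <- pr$phi[pr$rows[[r]], pr$rows[[j]]]
    if (any(M != 0)) {
      expect_lt(max(abs(rowMeans(M))), 1e-12)
      expect_lt(max(abs(colMeans(M))), 1e-12)
    }
  }
  expect_true(isSymmetric(pr$beta))
})

test_that("empty-graph samples are mutually independent", {
  cfg <- simulation_config(4, 2, 2, expected_degree = 0, n = 5000, seed = 2)
  m <- random_mixed_graph(cfg)
  ds <- sample_mixed_data(m, 5000, burn_in = 50, seed = 3)
  X <- as.matrix(ds$data[, 1:4])
  cr <- cor(X)
  expect_lt(max(abs(cr[upper.tri(cr)])), 0.05)
  # chi-square independence of the two categorical columns, Bonferroni-safe
  pv <- suppressWarnings(chisq.test(table(ds$data$D1, ds$data$D2))$p.value)
  expect_gt(pv, 0.05 / 16)
})

test_that("single-edge continuous pair matches the closed-form correlation", {
  # precision [[1, b], [b, 1]] implies correlation -b
  cfg <- simulation_config(2, 0, expected_degree = 1, n = 10000, seed = 7)
  m <- random_mixed_graph(cfg)
  b <- m$params$beta[1, 2]
  expect_true(abs(b) >= 0.5 * m$cc_rescale && abs(b) <= 1)
  ds <- sample_mixed_data(m, 10000, burn_in = 200, seed = 8)
  expect_lt(abs(cor(ds$data$C1, ds$data$C2) - (-b)), 0.03)
})

test_that("Gibbs sampling agrees with the exact Gaussian in the continuous case", {
  cfg <- simulation_config(5, 0, expected_degree = 2, n = 10000, seed = 11)
  m <- random_mixed_graph(cfg)
  Sigma <- solve(diag(5) + m$params$beta)
  ds <- sample_mixed_data(m, 10000, burn_in = 200, seed = 12)
  emp <- cov(as.matrix(ds$data))
  expect_lt(max(abs(emp - Sigma)), 0.05)
})

test_that("sampling is deterministic given config and seed", {
  cfg <- simulation_config(3, 2, 3, expected_degree = 2, n = 50, seed = 5)
  m1 <- random_mixed_graph(cfg)
  m2 <- random_mixed_graph(cfg)
  expect_true(graphs_equal(m1$graph, m2$graph))
  expect_identical(m1$params, m2$params)
  d1 <- sample_mixed_data(m1, 50, burn_in = 20, seed = 9)
  d2 <- sample_mixed_data(m2, 50, burn_in = 20, seed = 9)
  expect_identical(d1$data, d2$data)
  dag1 <- dag_model_for_pc(5, 2, seed = 4)
  dag2 <- dag_model_for_pc(5, 2, seed = 4)
  expect_true(graphs_equal(dag1$graph, dag2$graph))
  s1 <- sample_mixed_data(dag1, 30, seed = 6)
  s2 <- sample_mixed_data(dag2, 30, seed = 6)
  expect_identical(s1$data, s2$data)
})

test_that("single-chain Gibbs sampler runs, thins and is deterministic", {
  cfg <- simulation_config(2, 2, 2, expected_degree = 1.5, n = 40, seed = 15)
  m <- random_mixed_graph(cfg)
  d1 <- sample_mixed_data(m, 40, burn_in = 30, seed = 16,
                          chains = "single", thin = 5)
  d2 <- sample_mixed_data(m, 40, burn_in = 30, seed = 16,
                          chains = "single", thin = 5)
  expect_equal(d1$n, 40L)
  expect_identical(d1$data, d2$data)
  expect_false(identical(
    d1$data,
    sample_mixed_data(m, 40, burn_in = 30, seed = 17,
                      chains = "single", thin = 5)$data))
})

test_that("generator supports large sample draws", {
  cfg <- simulation_config(5, 0, expected_degree = 1, n = 20000, seed = 13)
  m <- random_mixed_graph(cfg)
  ds <- sample_mixed_data(m, 20000, burn_in = 50, seed = 14)
  expect_equal(ds$n, 20000L)
})

test_that("DAG collider shows marginal independence, dependence given the child", {
  set.seed(20)
  found <- FALSE
  for (sd in 1:50) {
    dm <- dag_model_for_pc(3, expected_degree = 1.3, seed = sd)
    de <- directed_edges(dm$graph)
    if (nrow(de) == 2 && length(unique(de[, "to"])) == 1 &&
        length(unique(de[, "from"])) == 2) { found <- TRUE; break }
  }
  expect_true(found)
  ds <- sample_mixed_data(dm, 5000, seed = 21)
  pa <- unique(de[, "from"]); ch <- de[1, "to"]
  r_marg <- ci_test(ds, pa[1], pa[2], character(), alpha = 0.05)
  r_cond <- ci_test(ds, pa[1], pa[2], ch, alpha = 0.05)
  expect_true(r_marg$independent)
  expect_false(r_cond$independent)
})

test_that("two-variable DAG with no edges yields independent columns", {
  dm <- dag_model_for_pc(2, expected_degree = 0, seed = 3)
  expect_equal(nrow(dm$graph$edges), 0L)
  ds <- sample_mixed_data(dm, 2000, seed = 4)
  expect_lt(abs(cor(ds$data[[1]], ds$data[[2]])), 0.06)
})

test_that("chain DAG satisfies X indep Z given Y at roughly the nominal rate", {
  # rejection rate of the true null X _||_ Z | Y approximates alpha
  rej <- vapply(1:200, function(sd) {
    ds <- chain_data(300, sd)
    !ci_test(ds, "X", "Z", "Y", alpha = 0.05)$independent
  }, logical(1))
  expect_gt(mean(rej), 0.01)
  expect_lt(mean(rej), 0.10)
})

test_that("d-separation pattern of a 4-node DAG motif is matched empirically", {
  # X -> Z <- Y, Z -> W : X _||_ Y; X dep W; X _||_ W | Z
  set.seed(34)
  n <- 5000
  X <- rnorm(n); Y <- rnorm(n)
  Z <- 0.8 * X + 0.8 * Y + rnorm(n)
  W <- 0.8 * Z + rnorm(n)
  ds <- as_dataset(data.frame(X = X, Y = Y, Z = Z, W = W))
  expect_true(ci_test(ds, "X", "Y")$independent)
  expect_false(ci_test(ds, "X", "W")$independent)
  expect_true(ci_test(ds, "X", "W", "Z")$independent)
  expect_false(ci_test(ds, "X", "Y", "Z")$independent)
})
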