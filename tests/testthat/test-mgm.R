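test_that("pseudo-likelihood at zero parameters has the closed form", {
  fx <- small_mixed_data(80, 3, 2, seed = 10)
  ds <- fx$dataset
  p0 <- mgm_params_init(ds)
  val <- negative_pseudo_loglik(p0, ds)
  X <- as.matrix(ds$data[, 1:3])
  expected <- sum(0.5 * colMeans(X^2) + 0.5 * log(2 * pi)) + 2 * log(3)
  expect_equal(val, expected, tolerance = 1e-12)
})

test_that("pseudo-likelihood equals the sum of node-wise regression losses", {
  fx <- small_mixed_data(60, 2, 2, seed = 11)
  ds <- fx$dataset
  p <- random_params(ds, seed = 12)
  total <- negative_pseudo_loglik(p, ds)
  n <- ds$n
  X <- as.matrix(ds$data[, 1:2])
  D <- matrix(0, n, 6)
  for (m in 1:2) D[cbind(1:n, (m - 1) * 3 + ds$data[[2 + m]])] <- 1
  nodewise <- 0
  for (s in 1:2) {
    eta <- p$alpha_c[s] + X %*% p$beta[, s] + D %*% p$rho[, s]
    nodewise <- nodewise + sum(0.5 * (X[, s] - eta)^2 + 0.5 * log(2 * pi)) / n
  }
  for (m in 1:2) {
    rj <- p$rows[[m]]
    S <- matrix(p$alpha_d[rj], n, 3, byrow = TRUE) +
      X %*% t(p$rho[rj, ]) + D %*% p$phi[, rj]
    lse <- log(rowSums(exp(S)))
    nodewise <- nodewise + sum(lse - S[cbind(1:n, ds$data[[2 + m]])]) / n
  }
  expect_equal(total, nodewise, tolerance = 1e-10)
})

test_that("analytic gradient matches central finite differences", {
  for (seed in c(21, 22)) {
    fx <- small_mixed_data(50, 3, 3, seed = seed)
    ds <- fx$dataset
    p <- random_params(ds, seed = seed + 100)
    g <- pseudo_loglik_gradient(p, ds)
    h <- 1e-5
    fd_free <- function(mutate) {
      pp <- mutate(p, h); f1 <- negative_pseudo_loglik(pp, ds)
      pm <- mutate(p, -h); f0 <- negative_pseudo_loglik(pm, ds)
      (f1 - f0) / (2 * h)
    }
    checks <- list(
      list(got = g$alpha_c[2], mut = function(q, d) {
        q$alpha_c[2] <- q$alpha_c[2] + d; q }),
      list(got = g$beta[1, 2], mut = function(q, d) {
        q$beta[1, 2] <- q$beta[1, 2] + d
        q$beta[2, 1] <- q$beta[2, 1] + d; q }),
      list(got = g$rho[2, 1], mut = function(q, d) {
        q$rho[2, 1] <- q$rho[2, 1] + d; q }),
      list(got = g$phi[1, 4], mut = function(q, d) {
        q$phi[1, 4] <- q$phi[1, 4] + d
        q$phi[4, 1] <- q$phi[4, 1] + d; q }),
      list(got = g$alpha_d[3], mut = function(q, d) {
        q$alpha_d[3] <- q$alpha_d[3] + d; q }))
    for (ck in checks) {
      fd <- fd_free(ck$mut)
      denom <- max(1e-8, abs(fd))
      expect_lt(abs(ck$got - fd) / denom, 1e-4)
    }
    expect_true(isSymmetric(g$beta))
    expect_true(isSymmetric(g$phi))
  }
})

test_that("gradient at zero with standardized data vanishes on intercepts", {
  fx <- small_mixed_data(100, 3, 1, seed = 31)
  ds <- fx$dataset
  g <- pseudo_loglik_gradient(mgm_params_init(ds), ds)
  expect_lt(max(abs(g$alpha_c)), 1e-10)
})

test_that("proximal operator matches the closed-form thresholds", {
  fx <- small_mixed_data(30, 2, 2, seed = 41)
  ds <- fx$dataset
  p <- random_params(ds, seed = 42, sd = 1)
  # identity at zero penalties
  p_id <- proximal_operator(p, lambda_triple(0, 0, 0), step = 0.5)
  expect_identical(p_id$beta, p$beta)
  expect_identical(p_id$rho, p$rho)
  # scalar soft-threshold: 3.0 with step*lambda = 1 -> 2.0
  p2 <- p; p2$beta[1, 2] <- p2$beta[1, 2] * 0 + 3; p2$beta[2, 1] <- 3
  out <- proximal_operator(p2, lambda_triple(2, 0, 0), step = 0.5)
  expect_equal(out$beta[1, 2], 2)
  # group threshold: small rho block becomes exactly zero
  p3 <- p
  p3$rho[p3$rows[[1]], 1] <- c(0.1, -0.05, 0.02)
  nv <- sqrt(sum(p3$rho[p3$rows[[1]], 1]^2))
  out3 <- proximal_operator(p3, lambda_triple(0, nv / 0.5 + 1, 0), step = 0.5)
  expect_identical(out3$rho[out3$rows[[1]], 1], c(0, 0, 0))
  # intercepts never penalized
  out4 <- proximal_operator(p, lambda_triple(10, 10, 10), step = 1)
  expect_identical(out4$alpha_c, p$alpha_c)
  expect_identical(out4$alpha_d, p$alpha_d)
})

test_that("huge penalties empty the graph; zero penalties fill it", {
  fx <- small_mixed_data(200, 3, 2, seed = 51)
  ds <- fx$dataset
  fit_hi <- fit_mgm(ds, lambda_triple(1e6))
  expect_equal(nrow(extract_graph(fit_hi)$edges), 0L)
  fit_lo <- fit_mgm(ds, lambda_triple(0), tol = 1e-7)
  g_lo <- extract_graph(fit_lo)
  expect_equal(nrow(g_lo$edges), choose(5, 2))
})

test_that("objective trace is non-increasing across seeds and penalties", {
  for (seed in c(61, 62)) {
    fx <- small_mixed_data(120, 3, 2, seed = seed)
    for (lam in c(0.05, 0.3)) {
      fit <- fit_mgm(fx$dataset, lambda_triple(lam))
      expect_true(all(diff(fit$objective_trace) <= 1e-10))
    }
    fit_plain <- fit_mgm(fx$dataset, lambda_triple(0.1), accelerate = FALSE)
    expect_true(all(diff(fit_plain$objective_trace) <= 1e-10))
  }
})

test_that("correlated continuous pair yields an edge, matching a lasso oracle", {
  skip_if_not_installed("glmnet")
  set.seed(71)
  n <- 1000
  x1 <- rnorm(n)
  x2 <- 0.8 * x1 + sqrt(1 - 0.64) * rnorm(n)
  x3 <- rnorm(n)
  ds <- as_dataset(data.frame(a = x1, b = x2, c = x3))
  fit <- fit_mgm(ds, lambda_triple(0.1), tol = 1e-7)
  g <- extract_graph(fit)
  expect_true(has_edge(g, "a", "b"))
  expect_false(has_edge(g, "a", "c") || has_edge(g, "b", "c"))
  # node-wise lasso on the same standardized problem agrees on the support
  Xs <- scale(cbind(x1, x2, x3))
  gl <- glmnet::glmnet(Xs[, -1], Xs[, 1], lambda = 0.1,
                       standardize = FALSE, intercept = TRUE)
  sup <- as.numeric(coef(gl))[-1] != 0
  expect_identical(sup, c(has_edge(g, "a", "b"), has_edge(g, "a", "c")))
})

test_that("continuous-only support agrees with neighborhood selection", {
  skip_if_not_installed("glmnet")
  cfg <- simulation_config(8, 0, expected_degree = 2, n = 600, seed = 81)
  m <- random_mixed_graph(cfg)
  ds <- sample_mixed_data(m, 600, burn_in = 150, seed = 82)
  lam <- 0.15
  fit <- fit_mgm(ds, lambda_triple(lam), tol = 1e-7)
  g <- extract_graph(fit)
  Xs <- scale(as.matrix(ds$data))
  agree <- 0; total <- 0
  # OR-rule neighborhood selection. Matched penalty is lam/2: each beta
  # entry appears in two node conditionals of the coupled objective, so
  # the per-regression lasso threshold is half the shared one (exact in
  # the bivariate case: beta_mgm = r - lam/2 vs beta_lasso = r - lam).
  nb <- matrix(FALSE, 8, 8)
  for (s in 1:8) {
    gl <- glmnet::glmnet(Xs[, -s], Xs[, s], lambda = lam / 2,
                         standardize = FALSE)
    w <- which(as.numeric(coef(gl))[-1] != 0)
    others <- (1:8)[-s]
    nb[s, others[w]] <- TRUE
  }
  for (s in 1:7) for (t in (s + 1):8) {
    total <- total + 1
    est <- has_edge(g, paste0("C", s), paste0("C", t))
    lasso_est <- nb[s, t] || nb[t, s]
    agree <- agree + (est == lasso_est)
  }
  expect_gte(agree / total, 0.95)
})

test_that("fitting handles pure-continuous and pure-categorical datasets", {
  cfg <- simulation_config(4, 0, expected_degree = 1.5, n = 200, seed = 95)
  mc <- random_mixed_graph(cfg)
  dc <- sample_mixed_data(mc, 200, burn_in = 100, seed = 96)
  fit_c <- fit_mgm(dc, lambda_triple(0.2))
  expect_true(all(diff(fit_c$objective_trace) <= 1e-10))
  expect_s3_class(extract_graph(fit_c), "endpoint_graph")

  cfgd <- simulation_config(0, 4, 3, expected_degree = 1.5, n = 200,
                            seed = 97)
  md <- random_mixed_graph(cfgd)
  dd <- sample_mixed_data(md, 200, burn_in = 100, seed = 98)
  fit_d <- fit_mgm(dd, lambda_triple(0.2))
  expect_true(all(diff(fit_d$objective_trace) <= 1e-10))
  g <- extract_graph(fit_d)
  expect_setequal(g$nodes, paste0("D", 1:4))
})

test_that("extract_graph reads block support exactly", {
  fx <- small_mixed_data(30, 2, 2, seed = 91)
  p <- mgm_params_init(fx$dataset)
  expect_equal(nrow(extract_graph(p)$edges), 0L)
  p$rho[p$rows[[1]], 2] <- c(0.5, -0.25, -0.25)
  g <- extract_graph(p)
  expect_equal(nrow(g$edges), 1L)
  expect_true(has_edge(g, "C2", "D1"))
  # fitted supports equal the prox zeros exactly
  fit <- fit_mgm(fx$dataset, lambda_triple(0.2))
  pe <- fit$params
  nz <- 0
  for (s in 1:2) for (m in 1:2) {
    v <- pe$rho[pe$rows[[m]], s]
    nrm <- sqrt(sum(v^2))
    expect_true(nrm == 0 || nrm > 1e-8)
    nz <- nz + (nrm > 0)
  }
  expect_equal(sum(vapply(seq_len(nrow(extract_graph(fit)$edges)),
                          function(i) 1L, integer(1))),
               nrow(extract_graph(fit)$edges))
})
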