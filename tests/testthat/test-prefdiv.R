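# Correlated continuous candidates with controlled association to a target.
prefdiv_fixture <- function(n = 400, seed = 1) {
  set.seed(seed)
  t0 <- rnorm(n)
  v1 <- 0.9 * t0 + sqrt(1 - 0.81) * rnorm(n)    # strong, unique
  v2 <- 0.8 * t0 + sqrt(1 - 0.64) * rnorm(n)    # strong
  v3 <- 0.95 * v2 + sqrt(1 - 0.9025) * rnorm(n) # redundant with v2
  v4 <- 0.5 * t0 + sqrt(0.75) * rnorm(n)
  v5 <- 0.9 * v1 + sqrt(1 - 0.81) * rnorm(n)    # redundant with v1
  v6 <- rnorm(n)                                 # noise
  as_dataset(data.frame(target = t0, v1 = v1, v2 = v2, v3 = v3,
                        v4 = v4, v5 = v5, v6 = v6))
}

# Independent reimplementation of the greedy rule for small problems:
# exhaustively follows the same sweep order over the scored list.
greedy_oracle <- function(dataset, target, k, tau) {
  cand <- setdiff(names(dataset$data), target)
  sc <- vapply(cand, function(v) abs(cor(dataset$data[[v]],
                                         dataset$data[[target]])), numeric(1))
  queue <- cand[order(-sc, cand)]
  sel <- character(0)
  i <- 1
  while (length(sel) < k && i <= length(queue)) {
    v <- queue[i]
    sims <- vapply(sel, function(r) abs(cor(dataset$data[[v]],
                                            dataset$data[[r]])), numeric(1))
    if (!length(sims) || max(sims) < tau) sel <- c(sel, v)
    i <- i + 1
  }
  sel
}

test_that("association scores behave for continuous and categorical targets", {
  ds <- prefdiv_fixture()
  # a variable is perfectly associated with itself
  d2 <- as_dataset(data.frame(t = ds$data$target, copy = ds$data$target,
                              o = rnorm(400)))
  expect_equal(target_association(d2, "copy", "t"), 1)
  # categorical target goes through 1 - p of the LRT, not correlation
  set.seed(5)
  n <- 400
  x <- rnorm(n)
  y <- as.integer(1 + (x + rnorm(n) > 0))
  d3 <- mixed_dataset(
    data.frame(x = x, noise = rnorm(n), y = y),
    list(variable_spec("x", "continuous"), variable_spec("noise", "continuous"),
         variable_spec("y", "categorical", levels = c("a", "b"))))
  s_signal <- target_association(d3, "x", "y")
  expect_gt(s_signal, 0.99)
  expect_true(target_association(d3, "noise", "y") <= 1)
})

test_that("null LRT association scores average about one half", {
  set.seed(6)
  reps <- 300
  n <- 300
  scores <- vapply(seq_len(reps), function(i) {
    x <- rnorm(n)
    y <- sample(2L, n, TRUE)
    ds <- mixed_dataset(
      data.frame(x = x, y = y),
      list(variable_spec("x", "continuous"),
           variable_spec("y", "categorical", levels = c("a", "b"))))
    target_association(ds, "x", "y")
  }, numeric(1))
  expect_lt(abs(mean(scores) - 0.5), 0.06)
})

test_that("pairwise similarity is absolute correlation", {
  set.seed(7)
  x <- rnorm(200)
  ds <- as_dataset(data.frame(a = x, b = 2 * x, c = -x, d = rnorm(200),
                              e = rnorm(200)))
  expect_equal(pairwise_similarity(ds, "a", "b"), 1)
  expect_equal(pairwise_similarity(ds, "a", "c"), 1)
  set.seed(8)
  big <- as_dataset(data.frame(u = rnorm(10000), v = rnorm(10000)))
  expect_lt(pairwise_similarity(big, "u", "v"), 0.05)
})

test_that("selection matches the exhaustive greedy oracle with clustering off", {
  for (seed in 1:4) {
    ds <- prefdiv_fixture(seed = seed)
    got <- prefdiv_select(ds, prefdiv_config("target", 3, cluster = FALSE,
                                             tau = 0.5))
    want <- greedy_oracle(ds, "target", 3, 0.5)
    expect_identical(got$selected, want)
  }
})

test_that("tau = 1 selects everything; categorical candidates always included", {
  ds <- prefdiv_fixture(seed = 9)
  got <- prefdiv_select(ds, prefdiv_config("target", 6, cluster = TRUE,
                                           tau = 1.0))
  expect_setequal(got$selected, paste0("v", 1:6))
  expect_true(all(lengths(got$clusters) == 0))
  # add a categorical candidate with no association at all
  set.seed(10)
  df <- ds$data
  df$grp <- sample(c("m", "f"), nrow(df), TRUE)
  ds2 <- as_dataset(df)
  got2 <- prefdiv_select(ds2, prefdiv_config("target", 2, tau = 0.5))
  expect_true("grp" %in% got2$selected)
})

test_that("selected continuous sets are never redundant and clusters partition", {
  for (seed in 11:13) {
    ds <- prefdiv_fixture(seed = seed)
    res <- prefdiv_select(ds, prefdiv_config("target", 4, cluster = TRUE,
                                             tau = 0.6))
    sel <- res$selected
    for (i in seq_along(sel)) for (j in seq_len(i - 1L))
      expect_lt(pairwise_similarity(ds, sel[i], sel[j]), 0.6)
    members <- unlist(res$clusters)
    expect_false(anyDuplicated(c(sel, members)) > 0)
    expect_length(intersect(sel, members), 0)
  }
})

test_that("raising tau never shrinks the selected representative set", {
  ds <- prefdiv_fixture(seed = 14)
  sizes <- vapply(c(0.3, 0.5, 0.7, 0.9), function(tau)
    length(prefdiv_select(ds, prefdiv_config("target", 4, tau = tau))$selected),
    numeric(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("stability threshold has the stated endpoint behavior", {
  set.seed(15)
  n <- 200
  base <- rnorm(n)
  ds <- as_dataset(data.frame(a = base, b = base, c = rnorm(n), d = rnorm(n)))
  tau <- stability_threshold(ds, c("a", "b", "c", "d"), B = 20, seed = 16)
  prof <- attr(tau, "profile")
  # duplicated pair: |r| = 1 at every tau, so always declared similar,
  # contributing zero instability; independent pairs stabilize at high tau
  expect_true(all(prof$instability >= 0 & prof$instability <= 0.5))
  expect_lte(prof$monotonized[nrow(prof)], 0.05)
  # recompute at the chosen tau with fresh subsamples
  set.seed(17)
  B <- 40; half <- n %/% 2
  M <- as.matrix(ds$data)
  cnt <- 0
  pairs <- combn(4, 2)
  theta <- numeric(ncol(pairs))
  for (b in seq_len(B)) {
    idx <- sample.int(n, half)
    r <- abs(cor(M[idx, ]))
    theta <- theta + (r[cbind(pairs[1, ], pairs[2, ])] >= as.numeric(tau))
  }
  theta <- theta / B
  expect_lte(mean(2 * theta * (1 - theta)), 0.05 + 0.02)
})

test_that("selection is deterministic and errors on a constant target", {
  ds <- prefdiv_fixture(seed = 18)
  a <- prefdiv_select(ds, prefdiv_config("target", 3, tau = 0.5))
  b <- prefdiv_select(ds, prefdiv_config("target", 3, tau = 0.5))
  expect_identical(a$selected, b$selected)
  df <- ds$data; df$target <- 1.0
  expect_error(prefdiv_select(suppressWarnings(as_dataset(df)),
                              prefdiv_config("target", 3, tau = 0.5)),
               "constant")
})
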