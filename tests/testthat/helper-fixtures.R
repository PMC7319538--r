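# Shared fixtures, built in code at test time.

# Continuous collider X -> Z <- Y with unit-variance noise.
collider_data <- function(n, seed, b = 0.7) {
  set.seed(seed)
  X <- rnorm(n); Y <- rnorm(n)
  Z <- b * X + b * Y + rnorm(n)
  as_dataset(data.frame(X = X, Y = Y, Z = Z))
}

# Continuous chain X -> Y -> Z.
chain_data <- function(n, seed, b = 0.8) {
  set.seed(seed)
  X <- rnorm(n)
  Y <- b * X + rnorm(n)
  Z <- b * Y + rnorm(n)
  as_dataset(data.frame(X = X, Y = Y, Z = Z))
}

# A random endpoint graph over nodes "V1".."Vp" with mixed edge kinds.
random_endpoint_graph <- function(p, seed, edge_prob = 0.3) {
  set.seed(seed)
  nodes <- paste0("V", seq_len(p))
  from <- to <- kind <- character(0)
  for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
    if (runif(1) < edge_prob) {
      from <- c(from, nodes[i]); to <- c(to, nodes[j])
      kind <- c(kind, sample(c("undir", "dir", "conf"), 1L))
    }
  }
  graph_from_edges(nodes, from, to, kind)
}

# Skeleton F1 between an estimated and a true graph.
skeleton_f1 <- function(est, truth) {
  ek <- paste(est$edges$a, est$edges$b)
  tk <- paste(truth$edges$a, truth$edges$b)
  tp <- sum(ek %in% tk)
  if (length(ek) == 0L || length(tk) == 0L) return(0)
  2 * tp / (length(ek) + length(tk))
}

# Random small mixed dataset with standardized continuous columns,
# used for gradient and objective checks.
small_mixed_data <- function(n, p_cont, p_disc, seed, levels = 3L) {
  cfg <- simulation_config(p_cont, p_disc, levels, expected_degree = 1.5,
                           n = n, seed = seed)
  m <- random_mixed_graph(cfg)
  ds <- sample_mixed_data(m, n, burn_in = 100L, seed = seed + 1L)
  for (k in seq_len(p_cont)) ds$data[[k]] <- as.numeric(scale(ds$data[[k]]))
  list(model = m, dataset = ds)
}

# Random parameters of matching shape, for gradient checks.
random_params <- function(dataset, seed, sd = 0.2) {
  set.seed(seed)
  p <- mgm_params_init(dataset)
  pc <- length(p$alpha_c)
  p$alpha_c <- rnorm(pc, 0, sd)
  if (pc) {
    B <- matrix(rnorm(pc * pc, 0, sd), pc, pc)
    B <- (B + t(B)) / 2; diag(B) <- 0
    p$beta <- B
  }
  if (nrow(p$rho)) p$rho <- matrix(rnorm(length(p$rho), 0, sd),
                                   nrow(p$rho), ncol(p$rho))
  if (nrow(p$phi)) {
    Ph <- matrix(rnorm(length(p$phi), 0, sd), nrow(p$phi), ncol(p$phi))
    Ph <- (Ph + t(Ph)) / 2
    for (m in seq_along(p$L)) Ph[p$rows[[m]], p$rows[[m]]] <- 0
    p$phi <- Ph
  }
  p$alpha_d <- rnorm(length(p$alpha_d), 0, sd)
  p
}
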