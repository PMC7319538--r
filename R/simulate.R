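#' Simulation configuration
#'
#' Settings for [random_mixed_graph()]: numbers of continuous and
#' categorical variables, levels per categorical variable, expected node
#' degree of the Erdős–Rényi graph, sample size, effect scale (edge
#' parameters are drawn uniformly from ±[0.5, 1]·`effect_scale`), Gibbs
#' burn-in sweeps and the seed.
#'
#' @param p_continuous,p_discrete Variable counts (sum must be >= 1).
#' @param levels Levels per categorical variable (>= 2).
#' @param expected_degree Expected node degree (>= 0, < p).
#' @param n Sample count.
#' @param effect_scale Multiplier on edge parameter magnitudes (> 0).
#' @param burn_in Gibbs burn-in sweeps.
#' @param seed Integer seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(p_continuous = 10L, p_discrete = 10L,
                              levels = 3L, expected_degree = 2,
                              n = 500L, effect_scale = 1,
                              burn_in = 200L, seed = 1L) {
  stopifnot(p_continuous >= 0L, p_discrete >= 0L,
            p_continuous + p_discrete >= 1L,
            levels >= 2L, expected_degree >= 0, n >= 1L,
            effect_scale > 0, burn_in >= 0L)
  structure(list(p_continuous = as.integer(p_continuous),
                 p_discrete = as.integer(p_discrete),
                 levels = as.integer(levels),
                 expected_degree = expected_degree,
                 n = as.integer(n), effect_scale = effect_scale,
                 burn_in = as.integer(burn_in), seed = as.integer(seed)),
            class = "simulation_config")
}

# Draw from ±[0.5, 1] * scale, uniform magnitude, random sign.
draw_effect <- function(k, scale) {
  stats::runif(k, 0.5, 1) * scale * sample(c(-1, 1), k, replace = TRUE)
}

#' Generate a random ground-truth mixed graphical model
#'
#' Draws an Erdős–Rényi undirected graph with edge probability
#' `expected_degree / (p - 1)` over `p_continuous + p_discrete` variables
#' and attaches pairwise potentials: a scalar for each
#' continuous–continuous edge (an off-diagonal entry of the continuous
#' precision block, whose diagonal is fixed at 1), a zero-sum vector over
#' levels for each continuous–categorical edge, and a doubly centered
#' matrix for each categorical–categorical edge. If the implied continuous
#' precision block `I + B` is not safely positive definite (smallest
#' eigenvalue below 0.2) the continuous–continuous block is rescaled so
#' the smallest eigenvalue equals 0.2; the factor is recorded in the
#' returned model as `cc_rescale`.
#'
#' @param config A [simulation_config()].
#' @return A `ground_truth_model` list with elements `graph` (undirected
#'   [endpoint_graph()]), `params`, `specs`, `seed` and `kind = "mgm"`.
#' @export
random_mixed_graph <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  pc <- config$p_continuous; pd <- config$p_discrete
  p <- pc + pd
  if (config$expected_degree >= p)
    stop("expected_degree must be smaller than the number of variables")
  set.seed(config$seed)
  q <- if (p > 1L) config$expected_degree / (p - 1) else 0
  cont_names <- if (pc) paste0("C", seq_len(pc)) else character(0)
  disc_names <- if (pd) paste0("D", seq_len(pd)) else character(0)
  nms <- c(cont_names, disc_names)
  L <- rep(config$levels, pd)
  rows <- if (pd) split(seq_len(sum(L)), rep(seq_len(pd), L)) else list()

  B <- matrix(0, pc, pc, dimnames = list(cont_names, cont_names))
  rho <- matrix(0, if (pd) sum(L) else 0L, pc)
  phi <- matrix(0, nrow(rho), nrow(rho))
  from <- to <- character(0)
  for (i in seq_len(max(p - 1L, 0L))) for (j in seq.int(i + 1L, p)) {
    if (stats::runif(1) >= q) next
    from <- c(from, nms[i]); to <- c(to, nms[j])
    ci <- i <= pc; cj <- j <= pc
    if (ci && cj) {
      B[i, j] <- B[j, i] <- draw_effect(1L, config$effect_scale)
    } else if (ci && !cj) {
      v <- draw_effect(L[j - pc], config$effect_scale)
      rho[rows[[j - pc]], i] <- v - mean(v)
    } else {
      M <- matrix(draw_effect(L[i - pc] * L[j - pc], config$effect_scale),
                  L[i - pc], L[j - pc])
      M <- M - rowMeans(M)
      M <- sweep(M, 2L, colMeans(M))
      phi[rows[[i - pc]], rows[[j - pc]]] <- M
      phi[rows[[j - pc]], rows[[i - pc]]] <- t(M)
    }
  }
  cc_rescale <- 1
  if (pc > 1L && any(B != 0)) {
    emin <- min(eigen(diag(pc) + B, symmetric = TRUE,
                      only.values = TRUE)$values)
    if (emin < 0.2) {
      embase <- min(eigen(B, symmetric = TRUE, only.values = TRUE)$values)
      cc_rescale <- 0.8 / abs(embase)
      B <- B * cc_rescale
    }
  }
  specs <- c(lapply(cont_names, variable_spec, vtype = "continuous"),
             lapply(seq_along(disc_names), function(m)
               variable_spec(disc_names[m], "categorical",
                             levels = paste0("l", seq_len(L[m])))))
  structure(list(
    graph = graph_from_edges(nms, from, to, "undir"),
    params = list(alpha_c = rep(0, pc), beta = B, rho = rho, phi = phi,
                  alpha_d = rep(0, nrow(rho)), rows = rows, L = L),
    specs = specs, seed = config$seed, kind = "mgm",
    cc_rescale = cc_rescale), class = "ground_truth_model")
}

# Row-wise categorical draw from unnormalized log-scores (n x L matrix).
sample_categorical <- function(scores) {
  pr <- exp(scores - apply(scores, 1L, max))
  pr <- pr / rowSums(pr)
  u <- stats::runif(nrow(pr))
  cum <- t(apply(pr, 1L, cumsum))
  1L + rowSums(cum < u)
}

#' Sample data from a ground-truth model
#'
#' For undirected (`kind = "mgm"`) models, samples by Gibbs sweeps over
#' the full conditionals: each continuous node is Gaussian with unit
#' variance and mean `alpha - B x + rho' d`; each categorical node is
#' multinomial-logistic over its levels. By default `n` independent
#' chains are run in parallel (vectorized across chains), each initialized
#' at zeros/uniform draws and burned in for `burn_in` sweeps, yielding
#' independent draws; `chains = "single"` instead runs one chain and keeps
#' every `thin`-th sweep after burn-in. For DAG models (`kind = "dag"`)
#' sampling is ancestral in topological order and `burn_in`/`thin` are
#' ignored.
#'
#' @param model A `ground_truth_model`.
#' @param n Number of samples.
#' @param burn_in Burn-in sweeps (default from the model's config, 200).
#' @param seed Integer seed.
#' @param chains `"parallel"` (default) or `"single"`.
#' @param thin Thinning interval for the single-chain sampler.
#' @return A [mixed_dataset()].
#' @export
sample_mixed_data <- function(model, n, burn_in = 200L, seed = 1L,
                              chains = c("parallel", "single"), thin = 10L) {
  stopifnot(inherits(model, "ground_truth_model"), n >= 1L)
  chains <- match.arg(chains)
  if (model$kind == "dag") return(sample_dag_data(model, n, seed))
  set.seed(seed)
  pr <- model$params
  pc <- length(pr$alpha_c); pd <- length(pr$L)
  if (chains == "single") {
    total <- burn_in + n * thin
    X1 <- matrix(0, 1L, pc)
    Y1 <- if (pd) matrix(sample.int(pr$L[1L], pd, replace = TRUE), 1L, pd)
          else matrix(integer(0), 1L, 0L)
    for (m in seq_len(pd)) Y1[1L, m] <- sample.int(pr$L[m], 1L)
    X <- matrix(0, n, pc); Y <- matrix(0L, n, pd)
    kept <- 0L
    for (sw in seq_len(total)) {
      st <- gibbs_sweep(X1, Y1, pr)
      X1 <- st$X; Y1 <- st$Y
      if (sw > burn_in && (sw - burn_in) %% thin == 0L) {
        kept <- kept + 1L
        if (pc) X[kept, ] <- X1
        if (pd) Y[kept, ] <- Y1
      }
    }
  } else {
    X <- matrix(0, n, pc)
    Y <- if (pd) vapply(seq_len(pd), function(m)
      sample.int(pr$L[m], n, replace = TRUE), integer(n)) else
        matrix(integer(0), n, 0L)
    if (pd && n == 1L) Y <- matrix(Y, 1L, pd)
    for (sw in seq_len(burn_in)) {
      st <- gibbs_sweep(X, Y, pr)
      X <- st$X; Y <- st$Y
    }
  }
  model_dataset(model, X, Y)
}

# One Gibbs sweep over all nodes for all chains at once.
gibbs_sweep <- function(X, Y, pr) {
  n <- nrow(X); pc <- ncol(X); pd <- length(pr$L)
  D <- matrix(0, n, nrow(pr$rho))
  for (m in seq_len(pd)) {
    start <- pr$rows[[m]][1L]
    D[cbind(seq_len(n), start + Y[, m] - 1L)] <- 1
  }
  for (s in seq_len(pc)) {
    mu <- pr$alpha_c[s] - X %*% pr$beta[, s] +
      (if (pd) D %*% pr$rho[, s] else 0)
    if (any(!is.finite(mu))) stop("non-finite linear predictor in Gibbs ",
                                  "update (parameter scale too large)")
    X[, s] <- mu + stats::rnorm(n)
  }
  for (m in seq_len(pd)) {
    rj <- pr$rows[[m]]
    sc <- matrix(pr$alpha_d[rj], n, length(rj), byrow = TRUE) +
      (if (pc) X %*% t(pr$rho[rj, , drop = FALSE]) else 0) +
      D %*% pr$phi[, rj, drop = FALSE]
    if (any(!is.finite(sc))) stop("non-finite linear predictor in Gibbs ",
                                  "update (parameter scale too large)")
    Y[, m] <- sample_categorical(sc)
    D[, rj] <- 0
    D[cbind(seq_len(n), rj[1L] + Y[, m] - 1L)] <- 1
  }
  list(X = X, Y = Y)
}

model_dataset <- function(model, X, Y) {
  cont <- vapply(model$specs, function(s) s$vtype == "continuous", logical(1))
  df <- vector("list", length(model$specs))
  ic <- 0L; id <- 0L
  for (k in seq_along(model$specs)) {
    if (cont[k]) { ic <- ic + 1L; df[[k]] <- X[, ic] }
    else { id <- id + 1L; df[[k]] <- as.integer(Y[, id]) }
  }
  names(df) <- vapply(model$specs, `[[`, character(1), "name")
  mixed_dataset(as.data.frame(df, check.names = FALSE), model$specs)
}

#' Generate a random DAG model for orientation benchmarks
#'
#' Draws a random topological order, then Erdős–Rényi edges respecting it
#' (edge probability `expected_degree / (p - 1)`). Continuous nodes follow
#' linear-Gaussian structural equations with unit noise variance;
#' categorical nodes follow multinomial-logistic structural equations.
#' Coefficients are drawn from ±[0.5, 1]·`effect_scale` (level-effect
#' vectors and matrices centered). Sampling is ancestral
#' (topological-order), so no Gibbs chain is involved.
#'
#' @param p Total number of variables (>= 2).
#' @param expected_degree Expected node degree.
#' @param effect_scale Coefficient magnitude multiplier.
#' @param seed Integer seed.
#' @param p_discrete Number of categorical variables among the `p`.
#' @param levels Levels per categorical variable.
#' @return A `ground_truth_model` with `kind = "dag"` and a directed
#'   [endpoint_graph()].
#' @export
dag_model_for_pc <- function(p, expected_degree = 2, effect_scale = 1,
                             seed = 1L, p_discrete = 0L, levels = 3L) {
  stopifnot(p >= 2L, p_discrete >= 0L, p_discrete <= p,
            expected_degree >= 0, expected_degree < p)
  set.seed(seed)
  pc <- p - p_discrete
  nms <- c(if (pc) paste0("C", seq_len(pc)) else character(0),
           if (p_discrete) paste0("D", seq_len(p_discrete)) else character(0))
  is_disc <- c(rep(FALSE, pc), rep(TRUE, p_discrete))
  ord <- sample.int(p)
  q <- expected_degree / (p - 1)
  parents <- stats::setNames(vector("list", p), nms)
  from <- to <- character(0)
  for (j in 2L:p) for (i in 1L:(j - 1L)) {
    if (stats::runif(1) < q) {
      pa <- ord[i]; ch <- ord[j]
      parents[[ch]] <- c(parents[[ch]], pa)
      from <- c(from, nms[pa]); to <- c(to, nms[ch])
    }
  }
  coefs <- stats::setNames(vector("list", p), nms)
  for (ch in seq_len(p)) {
    cs <- list()
    for (pa in parents[[ch]]) {
      key <- nms[pa]
      if (!is_disc[ch] && !is_disc[pa]) {
        cs[[key]] <- draw_effect(1L, effect_scale)
      } else if (!is_disc[ch] && is_disc[pa]) {
        v <- draw_effect(levels, effect_scale); cs[[key]] <- v - mean(v)
      } else if (is_disc[ch] && !is_disc[pa]) {
        v <- draw_effect(levels, effect_scale); cs[[key]] <- v - mean(v)
      } else {
        M <- matrix(draw_effect(levels * levels, effect_scale),
                    levels, levels)
        M <- M - rowMeans(M); M <- sweep(M, 2L, colMeans(M))
        cs[[key]] <- M  # rows: parent level, cols: child level
      }
    }
    coefs[[ch]] <- cs
  }
  specs <- c(lapply(seq_len(pc), function(i)
    variable_spec(nms[i], "continuous")),
    lapply(which(is_disc), function(i)
      variable_spec(nms[i], "categorical",
                    levels = paste0("l", seq_len(levels)))))
  structure(list(
    graph = graph_from_edges(nms, from, to, "dir"),
    params = list(order = ord, parents = parents, coefs = coefs,
                  is_disc = is_disc, levels = levels, names = nms),
    specs = specs, seed = seed, kind = "dag"), class = "ground_truth_model")
}

sample_dag_data <- function(model, n, seed) {
  set.seed(seed)
  pr <- model$params
  p <- length(pr$names)
  vals <- stats::setNames(vector("list", p), pr$names)
  for (pos in seq_len(p)) {
    ch <- pr$order[pos]
    nm <- pr$names[ch]
    if (!pr$is_disc[ch]) {
      eta <- numeric(n)
      for (pa in pr$parents[[ch]]) {
        cf <- pr$coefs[[ch]][[pr$names[pa]]]
        eta <- eta + if (pr$is_disc[pa]) cf[vals[[pr$names[pa]]]]
                     else cf * vals[[pr$names[pa]]]
      }
      vals[[nm]] <- eta + stats::rnorm(n)
    } else {
      sc <- matrix(0, n, pr$levels)
      for (pa in pr$parents[[ch]]) {
        cf <- pr$coefs[[ch]][[pr$names[pa]]]
        sc <- sc + if (pr$is_disc[pa]) cf[vals[[pr$names[pa]]], , drop = FALSE]
                   else outer(vals[[pr$names[pa]]], rep(1, pr$levels)) *
                        matrix(cf, n, pr$levels, byrow = TRUE)
      }
      vals[[nm]] <- sample_categorical(sc)
    }
  }
  df <- as.data.frame(vals, check.names = FALSE)
  for (k in seq_len(p)) if (pr$is_disc[match(names(df)[k], pr$names)])
    df[[k]] <- as.integer(df[[k]])
  ord_specs <- model$specs[match(names(df),
    vapply(model$specs, `[[`, character(1), "name"))]
  mixed_dataset(df, ord_specs)
}
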