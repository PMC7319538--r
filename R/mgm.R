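#' Initialize MGM parameters at zero
#'
#' Builds the parameter blocks for a mixed graphical model over the
#' (non-constant) variables of a dataset: per-continuous-node intercepts
#' `alpha_c`, the symmetric continuous–continuous matrix `beta` (zero
#' diagonal), the continuous–categorical level-effect matrix `rho`
#' (rows indexed by stacked levels, columns by continuous variables), the
#' symmetric categorical–categorical block matrix `phi` (zero diagonal
#' blocks) and per-level intercepts `alpha_d`. Block metadata (`rows`,
#' `L`, variable names) is carried on the object.
#'
#' @param dataset A [mixed_dataset()].
#' @return An object of class `mgm_params`.
#' @export
mgm_params_init <- function(dataset) {
  bl <- split_blocks(dataset)
  pc <- ncol(bl$X); sumL <- bl$sumL
  structure(list(
    alpha_c = rep(0, pc),
    beta = matrix(0, pc, pc),
    rho = matrix(0, sumL, pc),
    phi = matrix(0, sumL, sumL),
    alpha_d = rep(0, sumL),
    cont_names = bl$cont_names, disc_names = bl$disc_names,
    rows = bl$rows, L = bl$L), class = "mgm_params")
}

#' Penalty weight triple
#'
#' The three nonnegative sparsity penalties of the mixed graphical model:
#' `lambda_cc` on continuous–continuous entries (lasso), `lambda_cd` on
#' continuous–categorical level vectors (group lasso, Euclidean norm) and
#' `lambda_dd` on categorical–categorical matrices (group lasso,
#' Frobenius norm).
#'
#' @param lambda_cc,lambda_cd,lambda_dd Nonnegative finite reals.
#' @return A `lambda_triple` list.
#' @export
lambda_triple <- function(lambda_cc, lambda_cd = lambda_cc,
                          lambda_dd = lambda_cc) {
  stopifnot(is.finite(lambda_cc), is.finite(lambda_cd),
            is.finite(lambda_dd), lambda_cc >= 0, lambda_cd >= 0,
            lambda_dd >= 0)
  structure(list(lambda_cc = lambda_cc, lambda_cd = lambda_cd,
                 lambda_dd = lambda_dd), class = "lambda_triple")
}

# Shared linear predictors. Returns Eta (n x pc), scores per discrete node
# (list of n x L_j), and probabilities when requested.
mgm_predictors <- function(params, bl) {
  n <- nrow(bl$X)
  pc <- ncol(bl$X)
  Eta <- NULL
  if (pc) {
    Eta <- matrix(params$alpha_c, n, pc, byrow = TRUE) + bl$X %*% params$beta
    if (bl$sumL) Eta <- Eta + bl$D %*% params$rho
  }
  scores <- vector("list", length(bl$L))
  for (m in seq_along(bl$L)) {
    rj <- params$rows[[m]]
    S <- matrix(params$alpha_d[rj], n, length(rj), byrow = TRUE)
    if (pc) S <- S + bl$X %*% t(params$rho[rj, , drop = FALSE])
    S <- S + bl$D %*% params$phi[, rj, drop = FALSE]
    scores[[m]] <- S
  }
  list(Eta = Eta, scores = scores)
}

#' Negative log pseudo-likelihood of a mixed graphical model
#'
#' Average (over samples) of the sum over node conditionals: for each
#' continuous node, the Gaussian conditional negative log-likelihood with
#' unit conditional variance around its linear predictor; for each
#' categorical node, the multinomial-logistic negative log-likelihood of
#' its observed level given its level scores. Continuous columns are
#' expected to be standardized (as [fit_mgm()] does internally).
#'
#' @param params An `mgm_params` object.
#' @param dataset A [mixed_dataset()] matching the parameter shapes.
#' @return A single number.
#' @export
negative_pseudo_loglik <- function(params, dataset) {
  bl <- split_blocks(dataset)
  check_shapes(params, bl)
  pred <- mgm_predictors(params, bl)
  n <- dataset$n
  val <- 0
  if (ncol(bl$X)) {
    R <- pred$Eta - bl$X
    val <- val + sum(R * R) / (2 * n) + ncol(bl$X) * 0.5 * log(2 * pi)
  }
  for (m in seq_along(bl$L)) {
    S <- pred$scores[[m]]
    mx <- apply(S, 1L, max)
    lse <- mx + log(rowSums(exp(S - mx)))
    obs <- S[cbind(seq_len(n), bl$Y[, m])]
    val <- val + sum(lse - obs) / n
  }
  val
}

check_shapes <- function(params, bl) {
  if (length(params$alpha_c) != ncol(bl$X) ||
      nrow(params$rho) != bl$sumL ||
      !identical(unname(params$L), unname(bl$L)))
    stop("parameter shapes do not match the dataset")
  invisible(TRUE)
}

#' Gradient of the negative log pseudo-likelihood
#'
#' Exact analytic gradient in the free-parameter space: the symmetric
#' `beta` and `phi` blocks accumulate contributions from both node
#' conditionals in which they appear.
#'
#' @inheritParams negative_pseudo_loglik
#' @return An `mgm_params`-shaped gradient object.
#' @export
pseudo_loglik_gradient <- function(params, dataset) {
  bl <- split_blocks(dataset)
  check_shapes(params, bl)
  mgm_gradient_blocks(params, bl)
}

mgm_gradient_blocks <- function(params, bl) {
  n <- nrow(bl$X)
  pred <- mgm_predictors(params, bl)
  g <- params
  if (ncol(bl$X)) {
    R <- pred$Eta - bl$X
    g$alpha_c <- colMeans(R)
    M <- crossprod(bl$X, R) / n
    Gb <- M + t(M)
    diag(Gb) <- 0
    g$beta <- Gb
  } else {
    R <- matrix(0, n, 0L)
  }
  G <- matrix(0, n, bl$sumL)
  for (m in seq_along(bl$L)) {
    S <- pred$scores[[m]]
    mx <- apply(S, 1L, max)
    P <- exp(S - mx); P <- P / rowSums(P)
    rj <- params$rows[[m]]
    G[, rj] <- P - bl$D[, rj, drop = FALSE]
  }
  if (bl$sumL) {
    g$alpha_d <- colMeans(G)
    if (ncol(bl$X))
      g$rho <- (crossprod(G, bl$X) + crossprod(bl$D, R)) / n
    A <- crossprod(bl$D, G) / n
    Gp <- A + t(A)
    for (m in seq_along(bl$L)) {
      rj <- params$rows[[m]]
      Gp[rj, rj] <- 0
    }
    g$phi <- Gp
  }
  g
}

#' Group soft-thresholding proximal operator
#'
#' Applies the proximal map of the three sparsity penalties blockwise:
#' lasso soft-thresholding on each `beta` entry with `step * lambda_cc`,
#' group (Euclidean-norm) shrinkage on each continuous–categorical level
#' vector with `step * lambda_cd`, and group (Frobenius-norm) shrinkage
#' on each categorical–categorical block with `step * lambda_dd`.
#' Intercepts are unpenalized. Blocks shrunk to or below the threshold
#' become exactly zero.
#'
#' @param params An `mgm_params` object.
#' @param lambdas A [lambda_triple()].
#' @param step Positive step size.
#' @return An `mgm_params` object.
#' @export
proximal_operator <- function(params, lambdas, step) {
  stopifnot(step > 0)
  p <- params
  t_cc <- step * lambdas$lambda_cc
  t_cd <- step * lambdas$lambda_cd
  t_dd <- step * lambdas$lambda_dd
  if (length(p$alpha_c) && t_cc > 0)
    p$beta <- sign(p$beta) * pmax(abs(p$beta) - t_cc, 0)
  if (length(p$alpha_c) && length(p$L) && t_cd > 0) {
    for (s in seq_along(p$alpha_c)) for (m in seq_along(p$L)) {
      rj <- p$rows[[m]]
      v <- p$rho[rj, s]
      nv <- sqrt(sum(v * v))
      p$rho[rj, s] <- if (nv <= t_cd) 0 else v * (1 - t_cd / nv)
    }
  }
  nd <- length(p$L)
  if (nd >= 2L && t_dd > 0) {
    for (r in 1L:(nd - 1L)) for (j in (r + 1L):nd) {
      rr <- p$rows[[r]]; rj <- p$rows[[j]]
      M <- p$phi[rr, rj, drop = FALSE]
      nm <- sqrt(sum(M * M))
      M <- if (nm <= t_dd) M * 0 else M * (1 - t_dd / nm)
      p$phi[rr, rj] <- M
      p$phi[rj, rr] <- t(M)
    }
  }
  p
}

# Identifiability centering: each rho level-vector to mean zero (shift
# absorbed by the continuous intercept), each phi block doubly centered
# (shifts absorbed by level intercepts). Leaves the smooth loss invariant
# and never increases the penalty.
center_params <- function(p) {
  for (m in seq_along(p$L)) {
    rj <- p$rows[[m]]
    for (s in seq_along(p$alpha_c)) {
      v <- p$rho[rj, s]
      cm <- mean(v)
      if (cm != 0) {
        p$rho[rj, s] <- v - cm
        p$alpha_c[s] <- p$alpha_c[s] + cm
      }
    }
  }
  nd <- length(p$L)
  if (nd >= 2L) for (r in 1L:(nd - 1L)) for (j in (r + 1L):nd) {
    rr <- p$rows[[r]]; rj <- p$rows[[j]]
    M <- p$phi[rr, rj, drop = FALSE]
    if (all(M == 0)) next
    rm <- rowMeans(M); cm <- colMeans(M); g <- mean(M)
    M2 <- M - matrix(rm, nrow(M), ncol(M)) -
      matrix(cm, nrow(M), ncol(M), byrow = TRUE) + g
    p$phi[rr, rj] <- M2
    p$phi[rj, rr] <- t(M2)
    p$alpha_d[rr] <- p$alpha_d[rr] + rm
    p$alpha_d[rj] <- p$alpha_d[rj] + (cm - g)
  }
  for (m in seq_along(p$L)) {
    rj <- p$rows[[m]]
    p$alpha_d[rj] <- p$alpha_d[rj] - mean(p$alpha_d[rj])
  }
  p
}

mgm_penalty <- function(p, lambdas) {
  val <- 0
  if (length(p$alpha_c) > 1L)
    val <- val + lambdas$lambda_cc * sum(abs(p$beta[upper.tri(p$beta)]))
  for (s in seq_along(p$alpha_c)) for (m in seq_along(p$L)) {
    v <- p$rho[p$rows[[m]], s]
    val <- val + lambdas$lambda_cd * sqrt(sum(v * v))
  }
  nd <- length(p$L)
  if (nd >= 2L) for (r in 1L:(nd - 1L)) for (j in (r + 1L):nd) {
    M <- p$phi[p$rows[[r]], p$rows[[j]], drop = FALSE]
    val <- val + lambdas$lambda_dd * sqrt(sum(M * M))
  }
  val
}

# Free-parameter linear combination a*P + b*Q and inner product; the
# symmetric matrices count each free entry once via masks.
p_lincomb <- function(a, P, b, Q) {
  for (f in c("alpha_c", "beta", "rho", "phi", "alpha_d"))
    P[[f]] <- a * P[[f]] + b * Q[[f]]
  P
}

p_dot <- function(P, Q) {
  val <- sum(P$alpha_c * Q$alpha_c) + sum(P$alpha_d * Q$alpha_d) +
    sum(P$rho * Q$rho)
  if (length(P$alpha_c) > 1L) {
    ut <- upper.tri(P$beta)
    val <- val + sum(P$beta[ut] * Q$beta[ut])
  }
  nd <- length(P$L)
  if (nd >= 2L) for (r in 1L:(nd - 1L)) for (j in (r + 1L):nd)
    val <- val + sum(P$phi[P$rows[[r]], P$rows[[j]]] *
                     Q$phi[Q$rows[[r]], Q$rows[[j]]])
  val
}

mgm_smooth_loss <- function(params, bl) {
  n <- nrow(bl$X)
  pred <- mgm_predictors(params, bl)
  val <- 0
  if (ncol(bl$X)) {
    R <- pred$Eta - bl$X
    val <- val + sum(R * R) / (2 * n) + ncol(bl$X) * 0.5 * log(2 * pi)
  }
  for (m in seq_along(bl$L)) {
    S <- pred$scores[[m]]
    mx <- apply(S, 1L, max)
    lse <- mx + log(rowSums(exp(S - mx)))
    obs <- S[cbind(seq_len(n), bl$Y[, m])]
    val <- val + sum(lse - obs) / n
  }
  val
}

#' Fit a sparse mixed graphical model
#'
#' Minimizes the penalized negative log pseudo-likelihood by proximal
#' gradient descent with FISTA acceleration (monotone restart: if an
#' accelerated step would raise the objective, the momentum is reset and
#' a plain proximal step is taken, so the objective trace is
#' non-increasing). The step size is chosen by backtracking line search
#' against the quadratic majorization condition. Continuous columns are
#' standardized internally before fitting; conditional variances are
#' fixed at one.
#'
#' @param dataset A [mixed_dataset()] with n >= 2.
#' @param lambdas A [lambda_triple()] (default 0.25 on all three edge
#'   types; automatic selection via [steps_select()] is recommended).
#' @param tol Relative objective-change convergence tolerance.
#' @param max_iter Iteration cap.
#' @param accelerate Use FISTA momentum (default TRUE).
#' @param init Optional `mgm_params` warm start.
#' @return An object of class `mgm_fit` with elements `params`,
#'   `objective_trace`, `converged`, `iterations` and `lambdas`.
#' @export
fit_mgm <- function(dataset, lambdas = lambda_triple(0.25), tol = 1e-5,
                    max_iter = 1000L, accelerate = TRUE, init = NULL) {
  stopifnot(inherits(dataset, "mixed_dataset"), dataset$n >= 2L)
  bl <- split_blocks(dataset, standardize = TRUE)
  x <- if (is.null(init)) {
    p0 <- structure(list(
      alpha_c = rep(0, ncol(bl$X)),
      beta = matrix(0, ncol(bl$X), ncol(bl$X)),
      rho = matrix(0, bl$sumL, ncol(bl$X)),
      phi = matrix(0, bl$sumL, bl$sumL),
      alpha_d = rep(0, bl$sumL),
      cont_names = bl$cont_names, disc_names = bl$disc_names,
      rows = bl$rows, L = bl$L), class = "mgm_params")
    p0
  } else init
  check_shapes(x, bl)
  obj <- function(p) mgm_smooth_loss(p, bl) + mgm_penalty(p, lambdas)
  Fx <- obj(x)
  if (!is.finite(Fx)) stop("non-finite objective at initialization")
  trace <- Fx
  x_prev <- x
  tk <- 1        # FISTA momentum variable
  step <- 1
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    # extrapolated point
    if (accelerate && iter > 1L) {
      t_next <- (1 + sqrt(1 + 4 * tk^2)) / 2
      w <- (tk - 1) / t_next
      y <- p_lincomb(1 + w, x, -w, x_prev)
      tk <- t_next
    } else {
      y <- x
      tk <- 1
    }
    stepped <- prox_step(y, bl, lambdas, step)
    Fnew <- mgm_smooth_loss(stepped$x, bl) + mgm_penalty(stepped$x, lambdas)
    if (!is.finite(Fnew)) stop("non-finite objective at iteration ", iter)
    if (Fnew > Fx + 1e-12) {
      # monotone restart: plain proximal step from x
      tk <- 1
      stepped <- prox_step(x, bl, lambdas, stepped$step)
      Fnew <- mgm_smooth_loss(stepped$x, bl) + mgm_penalty(stepped$x, lambdas)
    }
    step <- stepped$step * 2   # allow the step to grow back
    x_prev <- x
    x <- center_params(stepped$x)
    Fcent <- mgm_smooth_loss(x, bl) + mgm_penalty(x, lambdas)
    Fnew <- min(Fnew, Fcent)
    trace <- c(trace, Fnew)
    if (abs(Fx - Fnew) / max(1, abs(Fx)) < tol) {
      Fx <- Fnew
      converged <- TRUE
      break
    }
    Fx <- Fnew
  }
  structure(list(params = x, objective_trace = trace,
                 converged = converged, iterations = iter,
                 lambdas = lambdas),
            class = "mgm_fit")
}

# One backtracked proximal step from y; returns the accepted point and
# the step size that satisfied the majorization condition.
prox_step <- function(y, bl, lambdas, step) {
  gy <- mgm_smooth_loss(y, bl)
  grad <- mgm_gradient_blocks(y, bl)
  repeat {
    cand <- p_lincomb(1, y, -step, grad)
    cand <- proximal_operator(cand, lambdas, step)
    diff <- p_lincomb(1, cand, -1, y)
    rhs <- gy + p_dot(grad, diff) + p_dot(diff, diff) / (2 * step)
    if (mgm_smooth_loss(cand, bl) <= rhs + 1e-12 || step < 1e-12)
      return(list(x = cand, step = step))
    step <- step / 2
  }
}

#' @export
print.mgm_fit <- function(x, ...) {
  cat("mgm_fit: ", x$iterations, " iterations, ",
      if (x$converged) "converged" else "not converged",
      ", objective ", format(utils::tail(x$objective_trace, 1L)),
      "\n", sep = "")
  invisible(x)
}

#' Extract the undirected graph from MGM parameters
#'
#' An edge is present between two variables when the corresponding
#' parameter block norm (absolute value for continuous–continuous,
#' Euclidean norm for continuous–categorical, Frobenius norm for
#' categorical–categorical) exceeds `eps`. All edges are tail–tail.
#'
#' @param params An `mgm_params` object (e.g. from [fit_mgm()]).
#' @param eps Nonnegative threshold (default 1e-8).
#' @return An [endpoint_graph()] over the modeled variables.
#' @export
extract_graph <- function(params, eps = 1e-8) {
  if (inherits(params, "mgm_fit")) params <- params$params
  stopifnot(eps >= 0)
  cn <- params$cont_names; dn <- params$disc_names
  pc <- length(cn); nd <- length(dn)
  from <- to <- character(0)
  if (pc >= 2L) for (s in 1L:(pc - 1L)) for (t in (s + 1L):pc)
    if (abs(params$beta[s, t]) > eps) {
      from <- c(from, cn[s]); to <- c(to, cn[t])
    }
  for (s in seq_len(pc)) for (m in seq_len(nd)) {
    v <- params$rho[params$rows[[m]], s]
    if (sqrt(sum(v * v)) > eps) {
      from <- c(from, cn[s]); to <- c(to, dn[m])
    }
  }
  if (nd >= 2L) for (r in 1L:(nd - 1L)) for (j in (r + 1L):nd) {
    M <- params$phi[params$rows[[r]], params$rows[[j]]]
    if (sqrt(sum(M * M)) > eps) {
      from <- c(from, dn[r]); to <- c(to, dn[j])
    }
  }
  graph_from_edges(c(cn, dn), from, to, "undir")
}
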