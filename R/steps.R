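#' Draw subsample index sets
#'
#' `N` subsamples of size `b` drawn without replacement, seeded. The
#' default size is `min(floor(10 * sqrt(n)), floor(0.75 * n))`.
#'
#' @param n Sample count.
#' @param b Subsample size (1 <= b <= n); `NULL` for the default.
#' @param N Number of subsamples (default 20).
#' @param seed Integer seed.
#' @return A list of `N` integer index vectors.
#' @export
subsample_indices <- function(n, b = NULL, N = 20L, seed = 1L) {
  if (is.null(b)) b <- min(floor(10 * sqrt(n)), floor(0.75 * n))
  b <- as.integer(max(b, 1L))
  if (b > n) stop("subsample size exceeds n")
  set.seed(seed)
  lapply(seq_len(N), function(i) sort(sample.int(n, b)))
}

# Possible pairs of a given edge type over named variables.
type_pairs <- function(edge_type, cont_names, disc_names) {
  pick2 <- function(v) {
    if (length(v) < 2L) return(NULL)
    m <- utils::combn(v, 2L)
    data.frame(a = m[1L, ], b = m[2L, ], stringsAsFactors = FALSE)
  }
  switch(edge_type,
    CC = pick2(cont_names),
    DD = pick2(disc_names),
    CD = if (length(cont_names) && length(disc_names))
      expand.grid(a = cont_names, b = disc_names,
                  stringsAsFactors = FALSE) else NULL,
    stop("edge_type must be CC, CD or DD"))
}

#' Per-edge-type instability across subsample graphs
#'
#' For every possible pair of the given type, `theta` is the fraction of
#' the graphs containing that edge; the instability is the mean over
#' pairs of `2 * theta * (1 - theta)` (in [0, 0.5]). Returns `NA` when
#' the type has no possible pairs.
#'
#' @param graphs List of [endpoint_graph()] objects over the same nodes.
#' @param edge_type `"CC"`, `"CD"` or `"DD"`.
#' @param cont_names,disc_names Continuous / categorical variable names.
#' @return Mean instability, or `NA_real_`.
#' @export
edge_instability <- function(graphs, edge_type, cont_names, disc_names) {
  pairs <- type_pairs(edge_type, cont_names, disc_names)
  if (is.null(pairs) || nrow(pairs) == 0L) return(NA_real_)
  N <- length(graphs)
  theta <- numeric(nrow(pairs))
  for (g in graphs) {
    key <- edge_key(g$edges$a, g$edges$b)
    theta <- theta + (edge_key(pairs$a, pairs$b) %in% key)
  }
  theta <- theta / N
  mean(2 * theta * (1 - theta))
}

#' StEPS configuration
#'
#' @param lambda_grid Ascending lambda grid (default 30 log-spaced values
#'   in [0.05, 0.9]).
#' @param gamma Instability bound in (0, 0.5) (default 0.05).
#' @param N Number of subsamples (default 20).
#' @param b Subsample size; `NULL` for the [subsample_indices()] default.
#' @param seed Integer seed.
#' @param mgm_tol,mgm_max_iter Convergence settings of the subsample MGM
#'   fits.
#' @return A `steps_config` list.
#' @export
steps_config <- function(lambda_grid = exp(seq(log(0.05), log(0.9),
                                               length.out = 30L)),
                         gamma = 0.05, N = 20L, b = NULL, seed = 1L,
                         mgm_tol = 1e-4, mgm_max_iter = 500L) {
  stopifnot(length(lambda_grid) >= 1L, !is.unsorted(lambda_grid),
            all(lambda_grid > 0), gamma > 0, gamma < 0.5, N >= 2L)
  structure(list(lambda_grid = lambda_grid, gamma = gamma,
                 N = as.integer(N), b = b, seed = as.integer(seed),
                 mgm_tol = mgm_tol, mgm_max_iter = as.integer(mgm_max_iter)),
            class = "steps_config")
}

#' StEPS: stability-based selection of the lambda triple
#'
#' Starting from the smallest grid value applied to all three edge types,
#' fits the MGM on each subsample at the current lambda triple and
#' computes per-type edge instability. A type whose instability exceeds
#' `gamma` has its lambda advanced to the next grid value; a type at or
#' below `gamma` is frozen at its current value. This repeats until all
#' types are frozen or the grid is exhausted (then the largest grid value
#' is used, with a warning). Frozen types keep their lambda while the
#' subsample fits are re-run at the updated mixed triple.
#'
#' @param dataset A [mixed_dataset()].
#' @param config A [steps_config()].
#' @return A `stability_profile` list: `chosen` ([lambda_triple()]),
#'   `profile` (data.frame of visited triples and per-type raw and
#'   monotonized instabilities), `gamma`, and the subsample count.
#' @export
steps_select <- function(dataset, config = steps_config()) {
  stopifnot(inherits(dataset, "mixed_dataset"),
            inherits(config, "steps_config"))
  grid <- config$lambda_grid
  idxs <- subsample_indices(dataset$n, b = config$b, N = config$N,
                            seed = config$seed)
  subsets <- lapply(idxs, function(ix)
    mixed_dataset(dataset$data[ix, , drop = FALSE], dataset$specs))
  bl <- split_blocks(dataset)
  types <- c("CC", "CD", "DD")
  applicable <- vapply(types, function(tp)
    !is.null(type_pairs(tp, bl$cont_names, bl$disc_names)), logical(1))
  pos <- stats::setNames(rep(1L, 3L), types)
  frozen <- stats::setNames(!applicable, types)
  prof <- list()
  warm <- vector("list", length(subsets))
  repeat {
    lam <- lambda_triple(grid[pos["CC"]], grid[pos["CD"]], grid[pos["DD"]])
    graphs <- vector("list", length(subsets))
    for (i in seq_along(subsets)) {
      fit <- fit_mgm(subsets[[i]], lam, tol = config$mgm_tol,
                     max_iter = config$mgm_max_iter, init = warm[[i]])
      warm[[i]] <- fit$params
      graphs[[i]] <- extract_graph(fit)
    }
    inst <- vapply(types, function(tp)
      if (applicable[tp])
        edge_instability(graphs, tp, bl$cont_names, bl$disc_names)
      else NA_real_, numeric(1))
    prof[[length(prof) + 1L]] <- c(lambda_cc = lam$lambda_cc,
                                   lambda_cd = lam$lambda_cd,
                                   lambda_dd = lam$lambda_dd,
                                   inst_cc = inst["CC"],
                                   inst_cd = inst["CD"],
                                   inst_dd = inst["DD"])
    moved <- FALSE
    for (tp in types) {
      if (frozen[tp]) next
      if (!is.na(inst[tp]) && inst[tp] <= config$gamma) {
        frozen[tp] <- TRUE
      } else if (pos[tp] < length(grid)) {
        pos[tp] <- pos[tp] + 1L
        moved <- TRUE
      } else {
        warning("grid exhausted for edge type ", tp,
                "; using largest lambda")
        frozen[tp] <- TRUE
      }
    }
    if (all(frozen) || !moved) break
  }
  profile <- as.data.frame(do.call(rbind, prof))
  names(profile) <- c("lambda_cc", "lambda_cd", "lambda_dd",
                      "inst_cc", "inst_cd", "inst_dd")
  for (col in c("inst_cc", "inst_cd", "inst_dd"))
    profile[[paste0("mono_", sub("inst_", "", col))]] <-
      rev(cummax(rev(ifelse(is.na(profile[[col]]), 0, profile[[col]]))))
  chosen <- lambda_triple(grid[pos["CC"]], grid[pos["CD"]], grid[pos["DD"]])
  structure(list(chosen = chosen, profile = profile,
                 gamma = config$gamma, N = config$N,
                 lambda_grid = grid), class = "stability_profile")
}

#' @export
print.stability_profile <- function(x, ...) {
  cat("stability_profile: chosen lambda = (",
      format(x$chosen$lambda_cc), ", ", format(x$chosen$lambda_cd), ", ",
      format(x$chosen$lambda_dd), "), gamma = ", x$gamma, "\n", sep = "")
  invisible(x)
}
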