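#' Association between a candidate variable and the target
#'
#' Continuous target: the absolute Pearson correlation. Categorical
#' target: `1 - p` where `p` is the p-value of the likelihood-ratio test
#' comparing an intercept-only multinomial-logistic model of the target
#' against one with the candidate as predictor (plain logistic when the
#' target is binary). Scores lie in [0, 1]; a constant candidate scores 0
#' with a warning.
#'
#' @param dataset A [mixed_dataset()].
#' @param var Continuous candidate variable name (categorical candidates
#'   bypass scoring in [prefdiv_select()]).
#' @param target Target variable name.
#' @return A score in [0, 1].
#' @export
target_association <- function(dataset, var, target) {
  stopifnot(var != target)
  v <- dataset$data[[var]]
  if (stats::sd(v) == 0) {
    warning("constant candidate '", var, "' scored 0")
    return(0)
  }
  if (is_continuous(dataset, target)) {
    tv <- dataset$data[[target]]
    if (stats::sd(tv) == 0) stop("target '", target, "' is constant")
    return(abs(stats::cor(v, tv)))
  }
  res <- multinomial_lrt(dataset, y = target, x = var)
  1 - res$p_value
}

#' Absolute-correlation similarity between two continuous variables
#'
#' @param dataset A [mixed_dataset()].
#' @param var_i,var_j Continuous variable names.
#' @return `|Pearson r|` in [0, 1]; 0 with a warning for a constant
#'   column.
#' @export
pairwise_similarity <- function(dataset, var_i, var_j) {
  stopifnot(is_continuous(dataset, var_i), is_continuous(dataset, var_j))
  a <- dataset$data[[var_i]]; b <- dataset$data[[var_j]]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("constant column in similarity; returning 0")
    return(0)
  }
  abs(stats::cor(a, b))
}

#' Stability-based redundancy threshold
#'
#' Chooses the marking threshold tau from subsampling stability: over `B`
#' half-sample subsamples, each candidate pair's similar-pair indicator
#' (`|r| >= tau`) is recorded for every tau on the grid 0.1 to 0.9 (step
#' 0.05); the instability of a tau is the mean over pairs of
#' `2 * theta * (1 - theta)` with theta the fraction of subsamples
#' declaring the pair similar. Instabilities are monotonized by a running
#' maximum from the sparse (large-tau) end, and the smallest tau whose
#' monotonized instability is at most `gamma` is returned (0.9 with a
#' warning when none qualifies).
#'
#' @param dataset A [mixed_dataset()].
#' @param candidates Continuous variable names (at least 2).
#' @param B Number of half-sample subsamples (>= 10, default 50).
#' @param gamma Instability bound (default 0.05).
#' @param seed Integer seed.
#' @return The chosen tau, with the profile attached as attribute
#'   `profile` (data.frame of tau, instability, monotonized).
#' @export
stability_threshold <- function(dataset, candidates, B = 50L,
                                gamma = 0.05, seed = 1L) {
  stopifnot(length(candidates) >= 2L, B >= 10L)
  set.seed(seed)
  n <- dataset$n
  half <- floor(n / 2)
  M <- as.matrix(dataset$data[, candidates, drop = FALSE])
  taus <- seq(0.1, 0.9, by = 0.05)
  np <- length(candidates) * (length(candidates) - 1L) / 2L
  counts <- matrix(0, length(taus), np)  # similar declarations per pair
  for (b in seq_len(B)) {
    idx <- sample.int(n, half)
    r <- abs(stats::cor(M[idx, , drop = FALSE]))
    rv <- r[upper.tri(r)]
    for (ti in seq_along(taus))
      counts[ti, ] <- counts[ti, ] + (rv >= taus[ti])
  }
  theta <- counts / B
  instab <- rowMeans(2 * theta * (1 - theta))
  mono <- rev(cummax(rev(instab)))  # running max from the large-tau end
  ok <- which(mono <= gamma)
  if (length(ok) == 0L) {
    warning("no tau meets the instability bound; returning 0.9")
    tau <- 0.9
  } else tau <- taus[min(ok)]
  attr(tau, "profile") <- data.frame(tau = taus, instability = instab,
                                     monotonized = mono)
  tau
}

#' Pref-Div configuration
#'
#' @param target Target variable name.
#' @param num_select Number of continuous variables to select.
#' @param cluster Keep marked variables as cluster members of their
#'   representative (TRUE) or drop them (FALSE).
#' @param tau Redundancy threshold in [0, 1], or `"auto"` for
#'   [stability_threshold()].
#' @param keep Continuous variables the user wants selected
#'   unconditionally (do not count against `num_select`).
#' @param seed Seed used when `tau = "auto"`.
#' @return A `prefdiv_config` list.
#' @export
prefdiv_config <- function(target, num_select, cluster = TRUE,
                           tau = "auto", keep = character(), seed = 1L) {
  if (!identical(tau, "auto"))
    stopifnot(is.numeric(tau), tau >= 0, tau <= 1)
  stopifnot(num_select >= 1L)
  structure(list(target = target, num_select = as.integer(num_select),
                 cluster = isTRUE(cluster), tau = tau,
                 keep = as.character(keep), seed = as.integer(seed)),
            class = "prefdiv_config")
}

#' Pref-Div feature selection
#'
#' Selects up to `num_select` continuous variables associated with the
#' target while suppressing redundancy. Categorical candidates and
#' user-kept variables are always selected (not counted against
#' `num_select`). Continuous candidates are scored by
#' [target_association()] and swept in descending score order (ties
#' broken lexicographically): a candidate whose similarity to an
#' already-selected continuous variable reaches tau is marked — appended
#' to the cluster of its representative (the earliest-selected qualifying
#' one; remaining ties by higher similarity) when `cluster = TRUE`, else
#' dropped. The working list is refilled with the next-best unused
#' candidates until `num_select` continuous variables are selected or
#' candidates run out (warning).
#'
#' @param dataset A [mixed_dataset()].
#' @param config A [prefdiv_config()].
#' @return A `prefdiv_result` list with `selected` (ordered names),
#'   `clusters` (named list per selected representative), `scores`
#'   (association score per scored candidate) and `tau`.
#' @export
prefdiv_select <- function(dataset, config) {
  stopifnot(inherits(config, "prefdiv_config"))
  vars <- variable_names(dataset)
  if (!config$target %in% vars) stop("target not in dataset")
  tv <- dataset$data[[config$target]]
  if (stats::sd(as.numeric(tv)) == 0) stop("target is constant")
  cand <- setdiff(vars, config$target)
  is_cont <- vapply(cand, function(v) is_continuous(dataset, v), logical(1))
  auto_in <- c(cand[!is_cont], intersect(config$keep, cand[is_cont]))
  cont_cand <- setdiff(cand[is_cont], config$keep)
  if (length(cont_cand) < config$num_select)
    warning("fewer continuous candidates than num_select")
  scores <- vapply(cont_cand, function(v)
    suppressWarnings(target_association(dataset, v, config$target)),
    numeric(1))
  ord <- order(-scores, cont_cand)
  queue <- cont_cand[ord]
  tau <- config$tau
  if (identical(tau, "auto")) {
    tau <- if (length(cont_cand) >= 2L)
      as.numeric(stability_threshold(dataset, cont_cand,
                                     seed = config$seed))
    else 0.9
  }
  selected_cont <- character(0)
  clusters <- list()
  for (v in auto_in) clusters[[v]] <- character(0)
  # representatives eligible for marking: previously selected continuous
  # variables, including user-kept continuous ones
  reps <- intersect(config$keep, cand[is_cont])
  pos <- 1L
  while (length(selected_cont) < config$num_select && pos <= length(queue)) {
    batch_end <- min(length(queue),
                     pos + (config$num_select - length(selected_cont)) - 1L)
    for (i in pos:batch_end) {
      v <- queue[i]
      sims <- vapply(reps, function(r)
        suppressWarnings(pairwise_similarity(dataset, v, r)), numeric(1))
      hit <- which(sims >= tau)
      if (length(hit)) {
        if (config$cluster) {
          best <- hit[order(hit, -sims[hit])][1L]  # earliest-selected first
          rep_name <- reps[best]
          clusters[[rep_name]] <- c(clusters[[rep_name]], v)
        }
      } else {
        selected_cont <- c(selected_cont, v)
        reps <- c(reps, v)
        if (is.null(clusters[[v]])) clusters[[v]] <- character(0)
      }
    }
    pos <- batch_end + 1L
  }
  if (length(selected_cont) < config$num_select)
    warning("candidates exhausted before reaching num_select")
  selected <- c(auto_in, selected_cont)
  structure(list(selected = selected, clusters = clusters[selected],
                 scores = scores, tau = tau), class = "prefdiv_result")
}

#' @export
print.prefdiv_result <- function(x, ...) {
  cat("prefdiv_result: ", length(x$selected), " selected (tau = ",
      format(x$tau), ")\n", sep = "")
  for (nm in names(x$clusters)) {
    mem <- x$clusters[[nm]]
    cat("  ", nm,
        if (length(mem)) paste0(" <- {", paste(mem, collapse = ", "), "}")
        else "", "\n", sep = "")
  }
  invisible(x)
}

#' Reduce a dataset to the Pref-Div selection plus the target
#'
#' @param dataset A [mixed_dataset()].
#' @param result A `prefdiv_result`.
#' @param target Target variable name to retain.
#' @return A [mixed_dataset()] restricted to the selected variables and
#'   the target.
#' @export
prefdiv_reduce <- function(dataset, result, target) {
  keep <- c(result$selected, target)
  idx <- match(keep, variable_names(dataset))
  mixed_dataset(dataset$data[, idx, drop = FALSE], dataset$specs[idx])
}
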