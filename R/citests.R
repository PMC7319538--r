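#' @keywords internal
ci_result <- function(p_value, statistic, test_kind, dof, alpha,
                      warning_msg = NULL) {
  structure(list(p_value = p_value, statistic = statistic,
                 test_kind = test_kind, dof = dof,
                 independent = is.finite(p_value) && p_value > alpha,
                 alpha = alpha, warning_msg = warning_msg),
            class = "ci_test_result")
}

#' @export
print.ci_test_result <- function(x, ...) {
  cat(x$test_kind, ": statistic = ", format(x$statistic),
      ", dof = ", x$dof, ", p = ", format(x$p_value),
      if (x$independent) " (independent)" else " (dependent)", "\n",
      sep = "")
  invisible(x)
}

# Design columns for a variable: the numeric column itself, or dummy
# indicators for all non-reference levels (reference = first level).
design_cols <- function(dataset, var) {
  s <- spec_of(dataset, var)
  v <- dataset$data[[var]]
  if (s$vtype == "continuous") {
    m <- matrix(as.numeric(v), ncol = 1L)
    colnames(m) <- var
    return(m)
  }
  L <- length(s$levels)
  m <- matrix(0, length(v), L - 1L)
  for (l in 2L:L) m[, l - 1L] <- as.numeric(v == l)
  colnames(m) <- paste0(var, ".", s$levels[-1L])
  m
}

design_matrix <- function(dataset, vars) {
  if (length(vars) == 0L)
    return(matrix(numeric(0), dataset$n, 0L))
  do.call(cbind, lapply(vars, design_cols, dataset = dataset))
}

# Drop columns that are constant or linearly dependent on earlier ones
# (QR pivoting); returns kept column indices.
nonaliased_cols <- function(M, base = NULL) {
  if (ncol(M) == 0L) return(integer(0))
  full <- cbind(base, M)
  qr_ <- qr(full)
  keep <- qr_$pivot[seq_len(qr_$rank)]
  keep <- keep[keep > ncol(base %||% matrix(0, nrow(M), 0L))]
  sort(keep - (if (is.null(base)) 0L else ncol(base)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Linear-regression conditional-independence test
#'
#' Ordinary least squares of a continuous response on the test variable
#' `x` and the conditioning set `Z` (categorical predictors
#' dummy-encoded, reference = first level), plus an intercept. When `x`
#' contributes one design column the test is the two-sided t-test on its
#' coefficient; when it contributes several dummy columns the partial
#' F-test of the group is used (identical to the squared t-test when the
#' group has one column). Aliased `x` columns are dropped with a warning;
#' if every `x` column is aliased (e.g. `x` constant) the p-value is 1.
#'
#' @param dataset A [mixed_dataset()].
#' @param response Name of the continuous response variable.
#' @param x Name of the tested predictor.
#' @param Z Character vector of conditioning variable names.
#' @param alpha Significance level recorded on the result (default 0.05).
#' @return A `ci_test_result`.
#' @export
regression_test_linear <- function(dataset, response, x, Z = character(),
                                   alpha = 0.05) {
  stopifnot(is_continuous(dataset, response))
  yv <- dataset$data[[response]]
  n <- dataset$n
  icept <- matrix(1, n, 1L)
  Zm <- design_matrix(dataset, Z)
  if (n - (1L + ncol(Zm) + ncol(design_matrix(dataset, x))) <= 0L)
    return(ci_result(NA_real_, NA_real_, "linear_t", 0L, alpha,
                     "no residual degrees of freedom; edge kept"))
  keepZ <- nonaliased_cols(Zm, base = icept)
  Zm <- Zm[, keepZ, drop = FALSE]
  Xm <- design_matrix(dataset, x)
  keepX <- nonaliased_cols(Xm, base = cbind(icept, Zm))
  if (length(keepX) < ncol(Xm))
    warning("aliased design columns for '", x, "' dropped")
  Xm <- Xm[, keepX, drop = FALSE]
  m <- ncol(Xm)
  if (m == 0L)
    return(ci_result(1, 0, "linear_t", 0L, alpha,
                     "all x columns aliased or constant"))
  fit_null <- stats::lm.fit(cbind(icept, Zm), yv)
  fit_full <- stats::lm.fit(cbind(icept, Zm, Xm), yv)
  df_resid <- n - fit_full$rank
  if (df_resid <= 0L)
    return(ci_result(NA_real_, NA_real_, "linear_t", 0L, alpha,
                     "no residual degrees of freedom; edge kept"))
  rss0 <- sum(fit_null$residuals^2)
  rss1 <- sum(fit_full$residuals^2)
  if (m == 1L) {
    # t-test on the single x coefficient
    Fstat <- max(rss0 - rss1, 0) / (rss1 / df_resid)
    tstat <- sqrt(Fstat) * sign(fit_full$coefficients[ncol(Zm) + 2L])
    p <- 2 * stats::pt(abs(tstat), df_resid, lower.tail = FALSE)
    return(ci_result(p, unname(tstat), "linear_t", df_resid, alpha))
  }
  Fstat <- max(rss0 - rss1, 0) / m / (rss1 / df_resid)
  p <- stats::pf(Fstat, m, df_resid, lower.tail = FALSE)
  ci_result(p, Fstat, "linear_F", df_resid, alpha)
}

#' Multinomial-logistic likelihood-ratio conditional-independence test
#'
#' Fits multinomial logistic regressions of a categorical `y` on
#' `(x, Z)` and on `Z` alone, and compares them by the likelihood-ratio
#' statistic `2 (loglik_full - loglik_null)`, referred to a chi-square
#' distribution with `(L_y - 1) * m` degrees of freedom, `m` the number
#' of non-aliased `x` design columns. Fits use [nnet::multinom()]; on
#' non-convergence the fit is retried with a tiny ridge (`decay = 1e-8`).
#'
#' @param dataset A [mixed_dataset()].
#' @param y Name of the categorical outcome.
#' @param x Name of the tested predictor (categorical or continuous).
#' @param Z Character vector of conditioning variable names.
#' @param alpha Significance level recorded on the result.
#' @return A `ci_test_result`.
#' @export
multinomial_lrt <- function(dataset, y, x, Z = character(), alpha = 0.05) {
  sy <- spec_of(dataset, y)
  stopifnot(sy$vtype == "categorical")
  n <- dataset$n
  yv <- factor(dataset$data[[y]], levels = seq_along(sy$levels))
  Ly <- length(sy$levels)
  icept <- matrix(1, n, 1L)
  Zm <- design_matrix(dataset, Z)
  Xm <- design_matrix(dataset, x)
  if (n - (1L + ncol(Zm) + ncol(Xm)) * (Ly - 1L) <= 0L)
    return(ci_result(NA_real_, NA_real_, "multinomial_lrt", 0L, alpha,
                     "insufficient degrees of freedom; edge kept"))
  keepZ <- nonaliased_cols(Zm, base = icept)
  Zm <- Zm[, keepZ, drop = FALSE]
  keepX <- nonaliased_cols(Xm, base = cbind(icept, Zm))
  Xm <- Xm[, keepX, drop = FALSE]
  m <- ncol(Xm)
  if (m == 0L)
    return(ci_result(1, 0, "multinomial_lrt", 0L, alpha,
                     "x constant or aliased given Z"))
  dof <- (Ly - 1L) * m
  ll_null <- multinom_loglik(yv, Zm)
  ll_full <- multinom_loglik(yv, cbind(Zm, Xm))
  stat <- max(2 * (ll_full - ll_null), 0)
  p <- stats::pchisq(stat, dof, lower.tail = FALSE)
  ci_result(p, stat, "multinomial_lrt", dof, alpha)
}

# Maximum log-likelihood of a multinomial logistic fit of y on predictors
# (intercept added by multinom's formula).
multinom_loglik <- function(yfac, M) {
  df <- if (ncol(M)) as.data.frame(M) else data.frame(row.names = seq_along(yfac))
  names(df) <- if (ncol(M)) paste0("v", seq_len(ncol(M))) else character(0)
  df$.y <- yfac
  fml <- if (ncol(M)) stats::as.formula(paste(".y ~",
    paste(names(df)[names(df) != ".y"], collapse = "+"))) else .y ~ 1
  fit <- nnet::multinom(fml, data = df, trace = FALSE, maxit = 500,
                        reltol = 1e-13, abstol = 1e-12)
  if (fit$convergence != 0) {
    warning("multinomial fit did not converge; ridge-stabilized refit")
    fit <- nnet::multinom(fml, data = df, trace = FALSE, maxit = 1000,
                          decay = 1e-8, reltol = 1e-13, abstol = 1e-12)
  }
  -fit$value  # multinom minimizes the negative log-likelihood
}

#' Conditional-independence test for mixed data
#'
#' Dispatch used by PC-Stable: when either variable is continuous it
#' becomes the response of a linear model (both continuous: the
#' lexicographically later name is the response; the test is symmetric in
#' theory) via [regression_test_linear()]; when both are categorical,
#' [multinomial_lrt()] is used. An untestable case (insufficient residual
#' degrees of freedom) returns `independent = FALSE` with a warning, so
#' the edge is kept.
#'
#' @param dataset A [mixed_dataset()].
#' @param x,y Variable names (distinct).
#' @param Z Character vector of conditioning variable names (excluding
#'   `x` and `y`).
#' @param alpha Significance level (default 0.05).
#' @return A `ci_test_result`.
#' @export
ci_test <- function(dataset, x, y, Z = character(), alpha = 0.05) {
  stopifnot(x != y, !(x %in% Z), !(y %in% Z), alpha > 0, alpha < 1)
  cx <- is_continuous(dataset, x)
  cy <- is_continuous(dataset, y)
  res <- if (cx && cy) {
    resp <- max(x, y); pred <- min(x, y)
    regression_test_linear(dataset, resp, pred, Z, alpha)
  } else if (cy) {
    regression_test_linear(dataset, y, x, Z, alpha)
  } else if (cx) {
    regression_test_linear(dataset, x, y, Z, alpha)
  } else {
    multinomial_lrt(dataset, y, x, Z, alpha)
  }
  if (is.na(res$p_value)) {
    warning("untestable pair (", x, ", ", y, " | ",
            paste(Z, collapse = ","), "): edge kept")
    res$independent <- FALSE
  }
  res
}
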