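#' Variable specification
#'
#' Describes one column of a mixed dataset: its name, whether it is
#' continuous or categorical, and (for categorical variables) the ordered
#' level labels. Level order is first appearance in the source data; the
#' first level is the reference level for dummy coding everywhere in the
#' package.
#'
#' @param name Variable name (single string).
#' @param vtype Either `"continuous"` or `"categorical"`.
#' @param levels Character vector of level labels; must be empty for
#'   continuous variables and have at least two unique entries for
#'   categorical ones.
#' @param constant Logical flag marking a constant column (kept in the
#'   dataset but excluded from model fitting by default).
#' @return An object of class `variable_spec`.
#' @export
variable_spec <- function(name, vtype = c("continuous", "categorical"),
                          levels = character(), constant = FALSE) {
  vtype <- match.arg(vtype)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  levels <- as.character(levels)
  if (vtype == "categorical") {
    if (length(levels) < 2L || anyDuplicated(levels))
      stop("categorical variable '", name, "' needs >= 2 unique levels")
  } else if (length(levels) > 0L) {
    stop("continuous variable '", name, "' must not carry levels")
  }
  structure(list(name = name, vtype = vtype, levels = levels,
                 constant = isTRUE(constant)),
            class = "variable_spec")
}

#' Mixed dataset container
#'
#' An n x p table of continuous and categorical variables. Continuous
#' columns are stored as numeric vectors; categorical columns as integer
#' level indices (1-based) into the level labels of the matching
#' [variable_spec()].
#'
#' @param data A data.frame whose columns are numeric (continuous) or
#'   integer codes (categorical).
#' @param specs List of [variable_spec()] objects, one per column, in
#'   column order.
#' @return An object of class `mixed_dataset` with elements `data`,
#'   `specs`, `n` and `p`.
#' @export
mixed_dataset <- function(data, specs) {
  stopifnot(is.data.frame(data), is.list(specs),
            length(specs) == ncol(data))
  nms <- vapply(specs, function(s) s$name, character(1))
  if (anyDuplicated(nms)) stop("duplicate variable names")
  if (!identical(names(data), nms)) names(data) <- nms
  if (nrow(data) < 1L || ncol(data) < 1L)
    stop("dataset must have at least one row and one column")
  if (anyNA(data)) stop("dataset contains missing values")
  for (k in seq_along(specs)) {
    s <- specs[[k]]
    col <- data[[k]]
    if (s$vtype == "categorical") {
      if (!all(col == as.integer(col)))
        stop("categorical column '", s$name, "' must hold integer codes")
      data[[k]] <- as.integer(col)
      if (any(col < 1L | col > length(s$levels)))
        stop("level index out of range in column '", s$name, "'")
    } else {
      data[[k]] <- as.numeric(col)
    }
  }
  structure(list(data = data, specs = specs,
                 n = nrow(data), p = ncol(data)),
            class = "mixed_dataset")
}

#' @export
print.mixed_dataset <- function(x, ...) {
  nc <- sum(vapply(x$specs, function(s) s$vtype == "continuous", logical(1)))
  cat("mixed_dataset: ", x$n, " samples x ", x$p, " variables (",
      nc, " continuous, ", x$p - nc, " categorical)\n", sep = "")
  invisible(x)
}

variable_names <- function(dataset) {
  vapply(dataset$specs, function(s) s$name, character(1))
}

spec_of <- function(dataset, var) {
  i <- match(var, variable_names(dataset))
  if (is.na(i)) stop("unknown variable '", var, "'")
  dataset$specs[[i]]
}

is_continuous <- function(dataset, var) {
  spec_of(dataset, var)$vtype == "continuous"
}

#' Infer the type of a raw data column
#'
#' A column is categorical when it contains any non-numeric token, or when
#' all entries are numeric, integral and take at most `max_levels` distinct
#' values. Otherwise it is continuous. Level order is first appearance.
#' The rule is deterministic and independent of row order in the sense
#' that the inferred type never changes with row order (only the level
#' ordering follows the rows as given).
#'
#' @param values Character (or numeric) vector of raw column values.
#' @param max_levels Maximum number of distinct integral values still
#'   treated as categorical (default 5).
#' @param name Variable name to attach to the returned spec.
#' @return A [variable_spec()].
#' @export
infer_variable_type <- function(values, max_levels = 5L, name = "x") {
  stopifnot(length(values) >= 1L, max_levels >= 1L)
  chr <- trimws(as.character(values))
  num <- suppressWarnings(as.numeric(chr))
  constant <- length(unique(chr)) == 1L
  if (constant)
    warning("column '", name, "' is constant; kept but excluded from models")
  if (anyNA(num)) {
    lev <- unique(chr)
    if (length(lev) < 2L) lev <- c(lev, paste0(lev, "_"))  # degenerate constant
    return(variable_spec(name, "categorical", levels = lev, constant = constant))
  }
  distinct <- unique(num)
  if (length(distinct) <= max_levels && all(num == round(num)) &&
      length(distinct) >= 2L) {
    return(variable_spec(name, "categorical",
                         levels = unique(chr), constant = constant))
  }
  variable_spec(name, "continuous", constant = constant)
}

#' Read a delimited mixed-type table
#'
#' Reads a delimited text file (header row required, unique column names),
#' infers per-column types with [infer_variable_type()], and returns a
#' [mixed_dataset()]. Categorical values are mapped to level indices in
#' first-appearance order. Missing cells are a load error (no imputation).
#'
#' @param path Path to the input file.
#' @param delimiter Field delimiter (default tab).
#' @param max_levels Passed to [infer_variable_type()].
#' @param type_hints Optional named character vector mapping column names
#'   to `"continuous"` or `"categorical"`, overriding inference.
#' @return A [mixed_dataset()].
#' @export
read_mixed_table <- function(path, delimiter = "\t", max_levels = 5L,
                             type_hints = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = delimiter,
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("NA", ""), comment.char = "",
                           quote = "\"")
  if (ncol(raw) < 1L) stop("no columns in ", path)
  if (nrow(raw) < 1L) stop("no data rows in ", path)
  if (anyDuplicated(names(raw))) stop("duplicate header names in ", path)
  as_dataset(raw, max_levels = max_levels, type_hints = type_hints)
}

#' Build a mixed dataset from an in-memory data.frame
#'
#' Applies the same type inference and level coding as [read_mixed_table()]
#' to a data.frame of raw values (character, numeric or factor columns).
#'
#' @inheritParams read_mixed_table
#' @param df A data.frame of raw values.
#' @return A [mixed_dataset()].
#' @export
as_dataset <- function(df, max_levels = 5L, type_hints = NULL) {
  stopifnot(is.data.frame(df))
  if (anyNA(df)) {
    idx <- which(is.na(as.matrix(df)), arr.ind = TRUE)[1L, ]
    stop("missing cell at row ", idx[1L], ", column '",
         names(df)[idx[2L]], "'")
  }
  specs <- vector("list", ncol(df))
  out <- vector("list", ncol(df))
  for (k in seq_len(ncol(df))) {
    nm <- names(df)[k]
    chr <- trimws(as.character(df[[k]]))
    sp <- infer_variable_type(chr, max_levels = max_levels, name = nm)
    if (!is.null(type_hints) && nm %in% names(type_hints)) {
      want <- match.arg(type_hints[[nm]], c("continuous", "categorical"))
      if (want != sp$vtype) {
        if (want == "categorical") {
          sp <- variable_spec(nm, "categorical", levels = unique(chr),
                              constant = sp$constant)
        } else {
          num <- suppressWarnings(as.numeric(chr))
          if (anyNA(num))
            stop("column '", nm, "' hinted continuous but holds ",
                 "non-numeric token '", chr[which(is.na(num))[1L]], "'")
          sp <- variable_spec(nm, "continuous", constant = sp$constant)
        }
      }
    }
    if (sp$vtype == "categorical") {
      code <- match(chr, sp$levels)
      if (anyNA(code)) stop("unmapped level in column '", nm, "'")
      out[[k]] <- as.integer(code)
    } else {
      num <- suppressWarnings(as.numeric(chr))
      if (anyNA(num))
        stop("non-numeric token '", chr[which(is.na(num))[1L]],
             "' in continuous column '", nm, "'")
      out[[k]] <- num
    }
    specs[[k]] <- sp
  }
  names(out) <- names(df)
  mixed_dataset(as.data.frame(out, check.names = FALSE), specs)
}

#' Write a mixed dataset to a delimited text file
#'
#' Categorical columns are written as their level labels.
#'
#' @param dataset A [mixed_dataset()].
#' @param path Output path.
#' @param delimiter Field delimiter (default tab).
#' @export
write_mixed_table <- function(dataset, path, delimiter = "\t") {
  df <- dataset$data
  for (k in seq_along(dataset$specs)) {
    s <- dataset$specs[[k]]
    if (s$vtype == "categorical") df[[k]] <- s$levels[df[[k]]]
  }
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Nonparanormal (Gaussian copula) transform
#'
#' Replaces each continuous column by the standard-normal quantiles of its
#' Winsorized empirical CDF ranks (truncation
#' \eqn{\delta = 1/(4 n^{1/4} \sqrt{\pi \log n})}), rescaled to the
#' column's original sample standard deviation. Ranks use average ties, so
#' the map is monotone and idempotent. Categorical and constant columns
#' are left untouched.
#'
#' @param dataset A [mixed_dataset()] with at least 3 rows.
#' @return A transformed [mixed_dataset()].
#' @export
nonparanormal_transform <- function(dataset) {
  stopifnot(inherits(dataset, "mixed_dataset"))
  n <- dataset$n
  if (n < 3L) stop("nonparanormal transform needs n >= 3")
  delta <- 1 / (4 * n^0.25 * sqrt(pi * log(n)))
  df <- dataset$data
  for (k in seq_along(dataset$specs)) {
    s <- dataset$specs[[k]]
    if (s$vtype != "continuous") next
    x <- df[[k]]
    sdx <- stats::sd(x)
    if (sdx == 0) {
      warning("constant continuous column '", s$name, "' left unchanged")
      next
    }
    r <- rank(x, ties.method = "average") / n
    z <- stats::qnorm(pmin(pmax(r, delta), 1 - delta))
    df[[k]] <- z / stats::sd(z) * sdx
  }
  mixed_dataset(df, dataset$specs)
}

# Internal: continuous design matrix (standardized on request) and one-hot
# coding of the categorical block, shared by mgm/simulate.
split_blocks <- function(dataset, standardize = FALSE, drop_constant = TRUE) {
  specs <- dataset$specs
  cont <- which(vapply(specs, function(s)
    s$vtype == "continuous" && !(drop_constant && s$constant), logical(1)))
  disc <- which(vapply(specs, function(s)
    s$vtype == "categorical" && !(drop_constant && s$constant), logical(1)))
  X <- as.matrix(dataset$data[, cont, drop = FALSE])
  storage.mode(X) <- "double"
  if (standardize && ncol(X) > 0L) {
    X <- scale(X)
    X[is.nan(X)] <- 0
    attr(X, "scaled:center") <- NULL
    attr(X, "scaled:scale") <- NULL
  }
  L <- vapply(disc, function(j) length(specs[[j]]$levels), integer(1))
  ends <- cumsum(L)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  rows <- lapply(seq_along(disc), function(m) starts[m]:ends[m])
  sumL <- if (length(L)) sum(L) else 0L
  Y <- as.matrix(dataset$data[, disc, drop = FALSE])
  storage.mode(Y) <- "integer"
  D <- matrix(0, dataset$n, sumL)
  for (m in seq_along(disc))
    D[cbind(seq_len(dataset$n), starts[m] + Y[, m] - 1L)] <- 1
  list(X = X, Y = Y, D = D,
       cont_idx = cont, disc_idx = disc,
       cont_names = vapply(specs[cont], `[[`, character(1), "name"),
       disc_names = vapply(specs[disc], `[[`, character(1), "name"),
       L = L, rows = rows, sumL = sumL)
}
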