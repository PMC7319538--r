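#' Pipeline run configuration
#'
#' Settings for [run_pipeline()]: the input table, an optional Pref-Div
#' pre-selection stage, the MGM penalties (exactly one of a fixed
#' [lambda_triple()] or automatic [steps_config()] selection), the
#' PC-Stable settings, an output prefix and the seed.
#'
#' @param input Path to a delimited input table (or a ready
#'   [mixed_dataset()]).
#' @param delimiter Field delimiter of the input file.
#' @param prefdiv Optional [prefdiv_config()]; `NULL` skips feature
#'   selection.
#' @param lambdas A [lambda_triple()], or `NULL` when `steps` is given.
#' @param steps A [steps_config()], or `NULL` when `lambdas` is given.
#' @param nonparanormal Apply [nonparanormal_transform()] to continuous
#'   columns before modeling.
#' @param alpha PC-Stable significance level.
#' @param max_depth PC-Stable conditioning-set cap.
#' @param out_prefix Output path prefix for artifacts.
#' @param seed Integer seed for the whole run.
#' @return A `run_config` list.
#' @export
run_config <- function(input, delimiter = "\t", prefdiv = NULL,
                       lambdas = lambda_triple(0.25), steps = NULL,
                       nonparanormal = FALSE, alpha = 0.05,
                       max_depth = Inf, out_prefix = "causalmix_run",
                       seed = 1L) {
  if (!is.null(lambdas) && !is.null(steps))
    stop("choose exactly one of fixed lambdas or StEPS selection")
  if (is.null(lambdas) && is.null(steps))
    stop("one of lambdas or steps must be given")
  structure(list(input = input, delimiter = delimiter, prefdiv = prefdiv,
                 lambdas = lambdas, steps = steps,
                 nonparanormal = isTRUE(nonparanormal), alpha = alpha,
                 max_depth = max_depth, out_prefix = out_prefix,
                 seed = as.integer(seed)), class = "run_config")
}

# Deterministic per-stage seed derived from the run seed and a label.
stage_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

#' Run the full causal-discovery pipeline
#'
#' Executes (optional) Pref-Div feature selection, (optional) StEPS
#' penalty selection, the MGM undirected fit, PC-Stable skeleton pruning
#' and orientation, and graph export. Writes
#' `<prefix>.undirected.sif`, `<prefix>.cpdag.sif`, `<prefix>.cpdag.json`
#' and `<prefix>.log` (parameters, seed and test counts). Deterministic
#' given the seed. On a stage failure, artifacts written so far are
#' renamed with a `.partial` suffix and the error is re-thrown with the
#' stage name.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the final `graph`, the `undirected`
#'   MGM graph, the `lambdas` used and the artifact paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  prefix <- config$out_prefix
  artifacts <- character(0)
  log_lines <- c(paste0("causalmix run, seed=", config$seed),
                 paste0("R version: ", R.version.string),
                 paste0("alpha=", config$alpha))
  stage <- "load"
  result <- tryCatch({
    dataset <- if (inherits(config$input, "mixed_dataset")) config$input
      else read_mixed_table(config$input, delimiter = config$delimiter)
    log_lines <- c(log_lines, paste0("loaded ", dataset$n, " x ",
                                     dataset$p, " dataset"))
    if (config$nonparanormal) {
      stage <- "nonparanormal"
      dataset <- nonparanormal_transform(dataset)
      log_lines <- c(log_lines, "nonparanormal transform applied")
    }
    if (!is.null(config$prefdiv)) {
      stage <- "prefdiv"
      pd_cfg <- config$prefdiv
      pd_cfg$seed <- stage_seed(config$seed, "prefdiv")
      pd <- prefdiv_select(dataset, pd_cfg)
      dataset <- prefdiv_reduce(dataset, pd, pd_cfg$target)
      log_lines <- c(log_lines,
                     paste0("prefdiv: tau=", format(pd$tau), "; selected ",
                            paste(pd$selected, collapse = ",")))
    }
    lambdas <- config$lambdas
    if (!is.null(config$steps)) {
      stage <- "steps"
      st_cfg <- config$steps
      st_cfg$seed <- stage_seed(config$seed, "steps")
      prof <- steps_select(dataset, st_cfg)
      lambdas <- prof$chosen
      log_lines <- c(log_lines, paste0("steps: gamma=", prof$gamma))
    }
    log_lines <- c(log_lines, paste0("lambdas=(",
      format(lambdas$lambda_cc), ",", format(lambdas$lambda_cd), ",",
      format(lambdas$lambda_dd), ")"))
    stage <- "mgm"
    fit <- fit_mgm(dataset, lambdas)
    undirected <- extract_graph(fit)
    f_und <- paste0(prefix, ".undirected.sif")
    write_sif(undirected, f_und)
    artifacts <- c(artifacts, f_und)
    log_lines <- c(log_lines, paste0("mgm: ", fit$iterations,
      " iterations, ", nrow(undirected$edges), " undirected edges"))
    stage <- "pcstable"
    sk <- pcs_skeleton(dataset, pc_config(alpha = config$alpha,
                                          max_depth = config$max_depth,
                                          initial_graph = undirected))
    graph <- apply_meek_rules(orient_colliders(sk$graph, sk$sepsets))
    log_lines <- c(log_lines, paste0("pcstable: ", sk$n_tests,
      " tests, ", nrow(graph$edges), " edges in CPDAG"))
    stage <- "export"
    f_sif <- paste0(prefix, ".cpdag.sif")
    f_json <- paste0(prefix, ".cpdag.json")
    write_sif(graph, f_sif)
    write_cytoscape_json(graph, f_json)
    artifacts <- c(artifacts, f_sif, f_json)
    f_log <- paste0(prefix, ".log")
    writeLines(log_lines, f_log)
    artifacts <- c(artifacts, f_log)
    list(graph = graph, undirected = undirected, lambdas = lambdas,
         artifacts = artifacts)
  }, error = function(err) {
    for (f in artifacts) if (file.exists(f))
      file.rename(f, paste0(f, ".partial"))
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(err), call. = FALSE)
  })
  invisible(result)
}
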